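# Stimulation protocols as deterministic event schedules. Every protocol
# starts with a 0.1 s pre-stimulus settling window so integration begins
# from the solver's rest state with margin.

new_protocol <- function(glu_times, bap_times, co_input, vgcc, duration, label) {
  stopifnot(
    all(glu_times >= 0), all(bap_times >= 0),
    all(diff(glu_times) >= 0), all(diff(bap_times) >= 0),
    !(co_input && length(bap_times) > 0) # rate vs STDP drive are exclusive
  )
  structure(
    list(
      glu_times = glu_times, bap_times = bap_times,
      co_input = co_input, vgcc = vgcc,
      duration = max(duration, glu_times, bap_times),
      label = label
    ),
    class = "spine_protocol"
  )
}

#' @export
print.spine_protocol <- function(x, ...) {
  cat(
    "<spine_protocol> ", x$label, "\n  ",
    length(x$glu_times), " glutamate event(s), ",
    length(x$bap_times), " bAP(s), duration ", signif(x$duration, 4), " s",
    if (x$co_input) ", dendritic co-input" else "",
    if (x$vgcc) ", VGCC enabled" else "", "\n",
    sep = ""
  )
  invisible(x)
}

settle_window <- function() 0.1

#' Unstimulated (quiet) protocol
#'
#' No events at all; used for rest-stability checks.
#'
#' @param duration total simulated time (s).
#' @return A `spine_protocol`.
#' @export
quiet_protocol <- function(duration = 100) {
  new_protocol(
    glu_times = numeric(0), bap_times = numeric(0),
    co_input = FALSE, vgcc = FALSE, duration = duration, label = "quiet"
  )
}

#' Unitary EPSP protocol
#'
#' A single glutamate pulse (after the 0.1 s settling window), no bAPs, no
#' dendritic co-input, VGCC disabled. The duration leaves room for the
#' delayed ER release (~up to 1 s after the pulse).
#'
#' @param duration total simulated time (s), at least 3 s.
#' @return A `spine_protocol`.
#' @export
unitary_epsp <- function(duration = 3) {
  new_protocol(
    glu_times = settle_window(), bap_times = numeric(0),
    co_input = FALSE, vgcc = FALSE,
    duration = max(duration, 3), label = "unitary EPSP"
  )
}

#' Regular presynaptic train (rate-dependent plasticity)
#'
#' `n_spikes` glutamate events at exact interval `1/f` (computed as `k/f`,
#' not by repeated addition), with the dendritic co-input drive enabled and
#' VGCC disabled.
#'
#' @param f input rate in Hz (0.1-20 in the standard protocol family).
#' @param n_spikes number of inputs (900 in the full protocol).
#' @param tail extra decay margin after the last event (s).
#' @return A `spine_protocol`.
#' @export
rate_train <- function(f, n_spikes = 900, tail = 2) {
  if (!is.numeric(f) || f <= 0) rlang::abort("input rate f must be positive")
  stopifnot(n_spikes >= 1)
  glu <- settle_window() + (seq_len(n_spikes) - 1) / f
  new_protocol(
    glu_times = glu, bap_times = numeric(0),
    co_input = TRUE, vgcc = FALSE,
    duration = max(glu) + tail,
    label = sprintf("rate train %g Hz x %d", f, n_spikes)
  )
}

#' Spike-timing pairing train (STDP)
#'
#' `n_pairings` pre/post pairings at 5 Hz. Within each pairing the (second)
#' bAP peak trails the glutamate pulse onset by `dt` ms (positive `dt` =
#' pre before post); with `n_bap = 2` the two bAPs are 10 ms apart and `dt`
#' references the second. The dendritic potential is the prescribed bAP
#' waveform (no co-input); VGCC is enabled.
#'
#' @param dt spike-timing difference in ms, within \[-100, 100\].
#' @param n_pairings number of pairings (100 in the full protocol).
#' @param n_bap bAPs per pairing (1 or 2).
#' @param pairing_rate pairing repetition rate (Hz).
#' @param tail decay margin after the last event (s).
#' @return A `spine_protocol`.
#' @export
stdp_train <- function(dt, n_pairings = 100, n_bap = 2, pairing_rate = 5,
                       tail = 2) {
  if (abs(dt) > 100) rlang::abort("spike-timing difference dt must be within [-100, 100] ms")
  if (!n_bap %in% c(1, 2)) rlang::abort("n_bap must be 1 or 2")
  stopifnot(n_pairings >= 1)
  dt_s <- dt / 1000
  block <- (seq_len(n_pairings) - 1) / pairing_rate
  # place events so every time is >= the settling window regardless of dt sign
  glu <- settle_window() + max(0, -dt_s) + block
  second_bap <- glu + dt_s
  bap <- if (n_bap == 2) sort(c(second_bap - 0.010, second_bap)) else second_bap
  # a leading first bAP of the first block may precede the settling window
  shift <- max(0, settle_window() - min(bap))
  new_protocol(
    glu_times = glu + shift, bap_times = bap + shift,
    co_input = FALSE, vgcc = TRUE,
    duration = max(glu, bap) + shift + tail,
    label = sprintf("STDP dt = %+g ms x %d (%d bAP)", dt, n_pairings, n_bap)
  )
}

#' Serialize / read a protocol event list
#'
#' Writes one event per line (`time kind`) plus header flags, a plain-text
#' format for audit and replay.
#'
#' @param protocol a `spine_protocol`.
#' @param path file path.
#' @return `path` (write) or a `spine_protocol` (read).
#' @export
write_protocol <- function(protocol, path) {
  lines <- c(
    paste0("# label: ", protocol$label),
    paste0("# co_input: ", protocol$co_input),
    paste0("# vgcc: ", protocol$vgcc),
    paste0("# duration: ", format(protocol$duration, digits = 17)),
    paste(format(protocol$glu_times, digits = 17), "glu"),
    if (length(protocol$bap_times) > 0) paste(format(protocol$bap_times, digits = 17), "bap")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  get <- function(key) sub(paste0("^# ", key, ": "), "", lines[grepl(paste0("^# ", key, ":"), lines)])
  ev <- strsplit(trimws(lines[!hdr & nzchar(lines)]), "\\s+")
  times <- vapply(ev, function(e) as.numeric(e[1]), numeric(1))
  kinds <- vapply(ev, function(e) e[2], character(1))
  new_protocol(
    glu_times = sort(times[kinds == "glu"]),
    bap_times = sort(times[kinds == "bap"]),
    co_input = as.logical(get("co_input")),
    vgcc = as.logical(get("vgcc")),
    duration = as.numeric(get("duration")),
    label = get("label")
  )
}
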
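#' Prospective gating parameters
#'
#' @param rr_interval R-R interval in seconds (time between ECG triggers).
#'   The default 0.150 s corresponds to 400 beats/min, the midpoint of a
#'   stabilized murine heart rate of 380-420 beats/min.
#' @param tr Repetition time in seconds.
#' @param block_size Number of consecutive half-projections played per
#'   block after each trigger (default 4).
#' @param gated Logical; `FALSE` describes a free-running (non-triggered)
#'   acquisition for which cine frame counts are undefined.
#' @return An object of class `gating_params`.
#' @export
gating_params <- function(rr_interval = 0.150, tr = 0.0035, block_size = 4L,
                          gated = TRUE) {
  if (rr_interval <= 0 || tr <= 0 || block_size < 1) {
    abort("rr_interval, tr must be > 0 and block_size >= 1.",
          class = "utecine_invalid_argument")
  }
  structure(
    list(rr_interval = rr_interval, tr = tr,
         block_size = as.integer(block_size), gated = isTRUE(gated)),
    class = "gating_params"
  )
}

#' @export
print.gating_params <- function(x, ...) {
  cat(sprintf("<gating_params> R-R %.4g s, TR %.4g s, block %d, %s\n",
              x$rr_interval, x$tr, x$block_size,
              if (x$gated) "ECG-gated" else "non-gated"))
  invisible(x)
}

#' Cine frame counts for the block-of-`block_size` encoding
#'
#' One block of `block_size` half-projections is replayed repeatedly along
#' the R-R interval. Each replay yields one high-spatial-resolution (HSR)
#' frame, so `n_hsr = floor(rr / (block_size * tr))`; splitting every block
#' into its individual slots yields `n_htr = block_size * n_hsr`
#' high-temporal-resolution (HTR) frames.
#'
#' @param g A [gating_params()] object with `gated = TRUE`.
#' @return A one-row tibble with `n_hsr` and `n_htr`.
#' @examples
#' frame_counts(gating_params(0.150, 0.0035, 4))  # 10 HSR / 40 HTR
#' @export
frame_counts <- function(g) {
  stopifnot(inherits(g, "gating_params"))
  if (!g$gated) {
    abort("frame counts are undefined for a non-gated acquisition.",
          class = "utecine_invalid_argument")
  }
  n_hsr <- floor(g$rr_interval / (g$block_size * g$tr))
  if (n_hsr < 1) abort("R-R interval shorter than one block.",
                       class = "utecine_invalid_argument")
  tibble(n_hsr = as.integer(n_hsr), n_htr = as.integer(g$block_size * n_hsr))
}

#' Build the prospective block-of-N acquisition schedule
#'
#' Heartbeat `h` acquires the block of projections
#' `{block_size*h, ..., block_size*h + block_size - 1}`, replayed once per
#' HSR frame along the R-R interval; the scan advances to the next block at
#' the next trigger.
#'
#' @param n_total Total number of distinct half-projections (divisible by
#'   `block_size`).
#' @param g A gated [gating_params()].
#' @return An object of class `acq_schedule`: list with `entries` (tibble
#'   with `heartbeat`, `frame`, `slot`, `projection`, `time`), `n_total`,
#'   `n_heartbeats`, `n_hsr`, `gating`. All indices are 0-based; `time` is
#'   seconds from the start of the scan.
#' @export
build_schedule <- function(n_total, g) {
  stopifnot(inherits(g, "gating_params"))
  if (n_total < 1 || n_total %% g$block_size != 0) {
    abort("`n_total` must be a positive multiple of block_size.",
          class = "utecine_invalid_argument")
  }
  fc <- frame_counts(g)
  bs <- g$block_size
  n_hb <- as.integer(n_total / bs)
  h <- rep(0:(n_hb - 1L), each = fc$n_hsr * bs)
  f <- rep(rep(0:(fc$n_hsr - 1L), each = bs), times = n_hb)
  s <- rep(0:(bs - 1L), times = n_hb * fc$n_hsr)
  entries <- tibble(
    heartbeat = h, frame = f, slot = s,
    projection = bs * h + s,
    time = h * g$rr_interval + (f * bs + s) * g$tr
  )
  structure(
    list(entries = entries, n_total = as.integer(n_total),
         n_heartbeats = n_hb, n_hsr = fc$n_hsr, gating = g),
    class = "acq_schedule"
  )
}

#' @export
print.acq_schedule <- function(x, ...) {
  cat(sprintf("<acq_schedule> %d projections / %d heartbeats / %d HSR frames (block %d)\n",
              x$n_total, x$n_heartbeats, x$n_hsr, x$gating$block_size))
  invisible(x)
}

#' @method tidy acq_schedule
#' @export
tidy.acq_schedule <- function(x, ...) x$entries

#' Bin scheduled projections into cine frames
#'
#' HSR mode: every HSR frame receives all `n_total` projections (the block
#' replays tile the sphere identically for each frame). HTR mode: frame
#' `f * block_size + s` receives the slot-`s` projection of every heartbeat
#' during replay `f`, i.e. `n_total / block_size` projections; the
#' `block_size` HTR children of one HSR frame partition its projection set.
#'
#' @param s An [build_schedule()] result.
#' @param mode `"hsr"` or `"htr"`.
#' @return A tibble of class `frame_binning` with columns `frame`,
#'   `time` (frame mid-time after the trigger, seconds), `n_projections`
#'   and `projections` (list-column of 0-based projection indices).
#' @export
bin_frames <- function(s, mode = c("hsr", "htr")) {
  stopifnot(inherits(s, "acq_schedule"))
  mode <- match.arg(tolower(mode), c("hsr", "htr"))
  bs <- s$gating$block_size
  tr <- s$gating$tr
  all_proj <- 0:(s$n_total - 1L)
  if (mode == "hsr") {
    out <- tibble(
      frame = 0:(s$n_hsr - 1L),
      time = (0:(s$n_hsr - 1L) + 0.5) * bs * tr,
      n_projections = s$n_total,
      projections = lapply(seq_len(s$n_hsr), function(i) all_proj)
    )
  } else {
    fr <- 0:(bs * s$n_hsr - 1L)
    slot <- fr %% bs
    out <- tibble(
      frame = fr,
      time = (fr + 0.5) * tr,
      n_projections = as.integer(s$n_total / bs),
      projections = lapply(fr, function(q) {
        sl <- q %% bs
        as.integer(seq(sl, s$n_total - 1L, by = bs))
      })
    )
  }
  class(out) <- c("frame_binning", class(out))
  attr(out, "mode") <- mode
  attr(out, "n_total") <- s$n_total
  out
}

#' Predicted total acquisition time
#'
#' Gated scans advance one block per heartbeat, so the scan lasts
#' `n_total / block_size` R-R intervals; non-gated scans play one
#' projection per TR back to back.
#'
#' @param n_total Total number of half-projections.
#' @param g A [gating_params()].
#' @param n_excitations Number of averages (default 1).
#' @return Scan time in seconds.
#' @examples
#' predicted_scan_time(51360, gating_params(tr = 0.0045, gated = FALSE))
#' predicted_scan_time(52540, gating_params(0.150, 0.0035, 4))
#' @export
predicted_scan_time <- function(n_total, g, n_excitations = 1) {
  stopifnot(inherits(g, "gating_params"))
  if (n_total < 1 || n_excitations < 1) {
    abort("`n_total` and `n_excitations` must be positive.",
          class = "utecine_invalid_argument")
  }
  if (g$gated) {
    if (n_total %% g$block_size != 0) {
      abort("`n_total` must be a multiple of block_size for a gated scan.",
            class = "utecine_invalid_argument")
    }
    (n_total / g$block_size) * g$rr_interval * n_excitations
  } else {
    n_total * g$tr * n_excitations
  }
}
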
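#' Describe one steady-state acquisition
#'
#' A single SPGR or bSSFP acquisition: flip angle, repetition and echo
#' time, RF phase increment (bSSFP phase cycling) and RF pulse duration.
#' Angles are given in degrees at the interface and stored in degrees
#' (flip) and radians (phase increment); all times are milliseconds.
#'
#' When `te_ms` is omitted it defaults to half the repetition time,
#' the convention used throughout: a common echo time for every
#' acquisition keeps bandwidth and distortion conditions equal, and in
#' a protocol built with [protocol()] the unset echo times are filled
#' with half the bSSFP repetition time.
#'
#' @param kind `"spgr"` or `"bssfp"`.
#' @param flip_deg prescribed flip angle (degrees, in (0, 180)).
#' @param tr_ms repetition time (ms, > 0).
#' @param te_ms echo time (ms, in (0, tr_ms)); `NULL` to use the default.
#' @param phi_rf_deg RF phase increment per TR (degrees; bSSFP only,
#'   ignored by the SPGR signal model).
#' @param t_rf_ms RF pulse duration (ms, >= 0), used by the finite-RF
#'   correction of the bSSFP transverse decay.
#' @return An object of class `jsr_sequence`.
#' @examples
#' sequence_spec("spgr", flip_deg = 18, tr_ms = 6.2)
#' sequence_spec("bssfp", flip_deg = 65, tr_ms = 4.2, phi_rf_deg = 180)
#' @export
sequence_spec <- function(kind = c("spgr", "bssfp"), flip_deg, tr_ms,
                          te_ms = NULL, phi_rf_deg = 0, t_rf_ms = 0) {
  kind <- match.arg(tolower(kind), c("spgr", "bssfp"))
  stopifnot(is.numeric(flip_deg), is.numeric(tr_ms), tr_ms > 0)
  if (flip_deg <= 0 || flip_deg >= 180)
    stop("flip_deg must lie strictly between 0 and 180 degrees")
  if (t_rf_ms < 0 || t_rf_ms >= tr_ms)
    stop("t_rf_ms must satisfy 0 <= t_rf_ms < tr_ms")
  if (!is.null(te_ms)) {
    if (te_ms <= 0 || te_ms >= tr_ms) stop("te_ms must satisfy 0 < te_ms < tr_ms")
  }
  structure(list(kind = kind, flip = flip_deg, tr = tr_ms, te = te_ms,
                 phi_rf = phi_rf_deg * pi / 180, t_rf = t_rf_ms),
            class = "jsr_sequence")
}

#' @export
print.jsr_sequence <- function(x, ...) {
  cat(format_sequence(x), "\n")
  invisible(x)
}

format_sequence <- function(x) {
  te <- if (is.null(x$te)) "0.5 TR(bSSFP)" else sprintf("%g ms", x$te)
  extra <- if (x$kind == "bssfp")
    sprintf(", phi_rf = %g deg", x$phi_rf * 180 / pi) else ""
  sprintf("%-5s flip %g deg, TR %g ms, TE %s%s, T_RF %g ms",
          x$kind, x$flip, x$tr, te, extra, x$t_rf)
}

#' Assemble an acquisition protocol
#'
#' An ordered collection of [sequence_spec()] acquisitions. Unset echo
#' times are filled with half the (smallest) bSSFP repetition time; if
#' the protocol holds no bSSFP entry, half of each entry's own TR is
#' used.
#'
#' @param ... `jsr_sequence` objects, or a single list of them.
#' @return An object of class `jsr_protocol` with attributes available
#'   through [n_spgr()], [n_bssfp()] and [total_tr()].
#' @seealso [baseline_protocol()], [validate_protocol()],
#'   [read_protocol()], [write_protocol()]
#' @export
protocol <- function(...) {
  seqs <- list(...)
  if (length(seqs) == 1 && is.list(seqs[[1]]) && !inherits(seqs[[1]], "jsr_sequence"))
    seqs <- seqs[[1]]
  if (length(seqs) == 0) stop("protocol needs at least one sequence")
  ok <- vapply(seqs, inherits, logical(1), "jsr_sequence")
  if (!all(ok)) stop("all protocol entries must be sequence_spec() objects")
  kinds <- vapply(seqs, `[[`, character(1), "kind")
  trb <- vapply(seqs[kinds == "bssfp"], `[[`, numeric(1), "tr")
  default_te <- if (length(trb)) 0.5 * min(trb) else NA_real_
  seqs <- lapply(seqs, function(s) {
    if (is.null(s$te)) {
      s$te <- if (is.na(default_te)) 0.5 * s$tr else default_te
      if (s$te >= s$tr)
        stop("default echo time 0.5*TR(bSSFP) exceeds the TR of: ", format_sequence(s))
    }
    s
  })
  structure(seqs, class = "jsr_protocol")
}

#' @export
print.jsr_protocol <- function(x, ...) {
  cat(sprintf("<protocol> %d SPGR + %d bSSFP, sum of TRs %.3g ms\n",
              n_spgr(x), n_bssfp(x), total_tr(x)))
  for (s in x) cat("  ", format_sequence(s), "\n", sep = "")
  invisible(x)
}

#' Protocol summaries
#'
#' Counts of SPGR and bSSFP acquisitions and the total of the repetition
#' times, the quantity a scan-time budget constrains (imaging time at
#' fixed resolution is proportional to the sum of TRs).
#'
#' @param p a `jsr_protocol`.
#' @return A count, or a time in ms.
#' @export
n_spgr <- function(p) sum(vapply(p, `[[`, character(1), "kind") == "spgr")

#' @rdname n_spgr
#' @export
n_bssfp <- function(p) sum(vapply(p, `[[`, character(1), "kind") == "bssfp")

#' @rdname n_spgr
#' @export
total_tr <- function(p) sum(vapply(p, `[[`, numeric(1), "tr"))

#' Check that a protocol can identify the joint model
#'
#' The joint model has five unknowns, so at least five data channels are
#' needed; and because all acquisitions share one echo time, at least two
#' bSSFP measurements (distinct phase cycles in practice) are required to
#' pin down the off-resonance map. Construction of smaller protocols is
#' allowed (pure simulation remains possible); this check is applied by
#' the fitting and design layers.
#'
#' @param p a `jsr_protocol`.
#' @param error if `TRUE` raise an error instead of returning `FALSE`.
#' @return `TRUE` if identifiable, otherwise `FALSE` (invisibly, with a
#'   message attribute) or an error.
#' @export
validate_protocol <- function(p, error = TRUE) {
  ns <- n_spgr(p); nb <- n_bssfp(p)
  msg <- NULL
  if (ns + nb < 5)
    msg <- sprintf("only %d acquisitions: at least 5 measurements are required for 5 unknowns", ns + nb)
  else if (nb < 2)
    msg <- "at least 2 bSSFP acquisitions are required to estimate off-resonance"
  if (is.null(msg)) return(TRUE)
  if (error) stop(msg) else {
    out <- FALSE
    attr(out, "reason") <- msg
    invisible(out)
  }
}

#' The published two-SPGR / four-bSSFP baseline protocol
#'
#' The reference DESPOT1/2-style protocol used throughout: two SPGR
#' acquisitions at 4 and 18 degrees with TR 6.2 ms, and four bSSFP
#' acquisitions at 15 and 65 degrees with TR 4.2 ms for phase increments
#' of 180 and 0 degrees. The sum of repetition times is 29.2 ms.
#'
#' @param t_rf_ms RF pulse duration applied to every entry (ms).
#' @return A `jsr_protocol`.
#' @export
baseline_protocol <- function(t_rf_ms = 0) {
  seqs <- c(
    lapply(c(4, 18), function(fa)
      sequence_spec("spgr", flip_deg = fa, tr_ms = 6.2, t_rf_ms = t_rf_ms)),
    unlist(lapply(c(180, 0), function(ph)
      lapply(c(15, 65), function(fa)
        sequence_spec("bssfp", flip_deg = fa, tr_ms = 4.2, phi_rf_deg = ph,
                      t_rf_ms = t_rf_ms))), recursive = FALSE))
  protocol(seqs)
}
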
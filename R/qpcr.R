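#' Relative qPCR expression by the 2^-ddCt method
#'
#' The per-condition reference Ct is the arithmetic mean of the reference
#' gene Cts (typically two housekeeping genes, e.g., GAPDH and ACTB).
#' dCt = target Ct - reference Ct; ddCt = dCt(damaged) - dCt(intact);
#' relative expression = 2^-ddCt (damaged relative to intact).
#'
#' @param ct_target numeric of length 2: target gene Ct in the damaged and
#'   intact condition, in that order (or named \code{damaged}/\code{intact}).
#' @param ct_refs_damaged numeric vector of reference-gene Cts in the
#'   damaged condition.
#' @param ct_refs_intact numeric vector of reference-gene Cts in the intact
#'   condition.
#' @return list with \code{relative_expression} (2^-ddCt), \code{dct}
#'   (per condition) and \code{ddct}.
#' @export
ddct_relative_expression <- function(ct_target, ct_refs_damaged,
                                     ct_refs_intact) {
  if (length(ct_target) != 2L)
    ps_stop("ct_target must give damaged and intact Ct values", "invalid_input")
  if (!is.null(names(ct_target)) && all(c("damaged", "intact") %in% names(ct_target)))
    ct_target <- ct_target[c("damaged", "intact")]
  vals <- c(ct_target, ct_refs_damaged, ct_refs_intact)
  if (length(ct_refs_damaged) == 0L || length(ct_refs_intact) == 0L)
    ps_stop("reference Ct values missing", "invalid_input")
  if (any(!is.finite(vals))) ps_stop("Ct values must be finite", "invalid_input")
  dct <- c(damaged = unname(ct_target[1]) - mean(ct_refs_damaged),
           intact = unname(ct_target[2]) - mean(ct_refs_intact))
  ddct <- unname(dct["damaged"] - dct["intact"])
  list(relative_expression = 2^(-ddct), dct = dct, ddct = ddct)
}
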
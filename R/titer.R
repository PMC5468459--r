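# Endpoint-titer arithmetic for agglutination assays.

#' Endpoint titer of a serial dilution
#'
#' The endpoint titer is the lowest protein concentration still producing
#' activity (agglutination); a lower endpoint means a stronger sample.
#'
#' @param concentration numeric vector of tested concentrations.
#' @param active logical vector, activity observed at each concentration.
#' @return the minimum active concentration.
#' @export
endpoint_titer <- function(concentration, active) {
  stopifnot(length(concentration) == length(active),
            all(concentration > 0))
  if (!any(active)) .fail("no active dilution; endpoint undefined")
  min(concentration[active])
}

#' Fold change between two endpoint titers
#'
#' Activity ratio of a test sample relative to a reference: the
#' reference endpoint concentration divided by the test endpoint
#' concentration, so a sample active at a 4-fold lower concentration has
#' fold change 4.
#'
#' @param reference endpoint concentration of the reference sample.
#' @param test endpoint concentration of the test sample.
#' @return numeric fold change (`> 1` means the test sample is stronger).
#' @examples
#' titer_fold_change(25, 6.25)        # 4
#' titer_fold_change(12.5, 0.03125)   # 400
#' @export
titer_fold_change <- function(reference, test) {
  stopifnot(is.numeric(reference), is.numeric(test),
            all(reference > 0), all(test > 0))
  reference / test
}
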
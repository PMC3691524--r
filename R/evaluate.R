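#' Classify predicted base pairs against a reference structure
#'
#' A predicted pair present in the reference is a true positive.  A
#' predicted pair absent from the reference is *compatible* when it
#' could be inserted into the reference without breaking pairing rules
#' -- it shares no endpoint with any reference pair and crosses none --
#' and *contradictory* (a false positive) otherwise.  Compatible pairs
#' are excluded from both the false-positive and the true-negative
#' counts by default (neither rewarded nor punished); set
#' `compatible_as_tn = TRUE` to count them as true negatives.
#'
#' True negatives are counted over the universe of all candidate pairs
#' `(i, j)` with `j - i > min_hairpin`.
#'
#' @param predicted,reference [rna_structure]s of equal length.
#' @param min_hairpin minimum pair separation defining the candidate
#'   universe (default 3).
#' @param compatible_as_tn count compatible predicted pairs as true
#'   negatives.
#' @return an object of class `pair_confusion`: list with integer
#'   fields `TP, FP, FN, TN, compatible`.
#' @export
classify_pairs <- function(predicted, reference, min_hairpin = 3L,
                           compatible_as_tn = FALSE) {
  stopifnot(inherits(predicted, "rna_structure"),
            inherits(reference, "rna_structure"))
  if (predicted$length != reference$length)
    stop("predicted and reference structures have different lengths")
  L <- predicted$length
  pk <- function(m) paste(m[, 1], m[, 2], sep = ":")
  pred <- predicted$pairs
  ref <- reference$pairs
  pred_keys <- pk(pred)
  ref_keys <- pk(ref)
  tp <- sum(pred_keys %in% ref_keys)
  fn <- sum(!(ref_keys %in% pred_keys))
  extra <- pred[!(pred_keys %in% ref_keys), , drop = FALSE]
  compat <- 0L
  fp <- 0L
  ref_idx <- c(ref)
  for (k in seq_len(nrow(extra))) {
    i <- extra[k, 1]; j <- extra[k, 2]
    if (i %in% ref_idx || j %in% ref_idx) { fp <- fp + 1L; next }
    crosses <- FALSE
    for (r in seq_len(nrow(ref))) {
      a <- ref[r, 1]; b <- ref[r, 2]
      if ((a < i && i < b) != (a < j && j < b)) { crosses <- TRUE; break }
    }
    if (crosses) fp <- fp + 1L else compat <- compat + 1L
  }
  universe <- sum(pmax(L - min_hairpin - seq_len(L), 0))
  tn <- universe - tp - fp - fn - (if (compatible_as_tn) 0L else compat)
  structure(list(TP = tp, FP = fp, FN = fn, TN = as.integer(tn),
                 compatible = compat),
            class = "pair_confusion")
}

#' @export
print.pair_confusion <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d  compatible %d  (MCC %.3f)\n",
              x$TP, x$FP, x$FN, x$TN, x$compatible, mcc(x)))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' common convention that a zero factor under the root gives 0.
#'
#' @param pc a `pair_confusion` (or list with fields `TP, FP, FN, TN`).
#' @return a value in `[-1, 1]`.
#' @export
mcc <- function(pc) {
  tp <- as.numeric(pc$TP); tn <- as.numeric(pc$TN)
  fp <- as.numeric(pc$FP); fn <- as.numeric(pc$FN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Sensitivity and specificity of base-pair prediction
#'
#' Sensitivity is `TP / (TP + FN)`.  "Specificity" follows the
#' base-pair-prediction convention `TP / (TP + FP)` (positive predictive
#' value): with the enormous true-negative universe of candidate pairs a
#' TN-based specificity saturates at 1 and carries no information.  Both
#' ratios return 1 on the degenerate 0/0 case (nothing to find / nothing
#' asserted is counted as fully correct).
#'
#' @param pc a `pair_confusion`.
#' @return named numeric vector `c(sensitivity =, specificity =)`.
#' @export
sensitivity_specificity <- function(pc) {
  sens <- if (pc$TP + pc$FN == 0) 1 else pc$TP / (pc$TP + pc$FN)
  spec <- if (pc$TP + pc$FP == 0) 1 else pc$TP / (pc$TP + pc$FP)
  c(sensitivity = sens, specificity = spec)
}

#' Evaluate a predicted structure against a reference
#'
#' Convenience wrapper combining [classify_pairs], [mcc] and
#' [sensitivity_specificity].
#'
#' @param predicted,reference [rna_structure]s or dot-bracket strings.
#' @inheritParams classify_pairs
#' @return a one-row data frame with columns `TP, FP, FN, TN,
#'   compatible, MCC, sensitivity, specificity`.
#' @export
evaluate_structure <- function(predicted, reference, min_hairpin = 3L,
                               compatible_as_tn = FALSE) {
  if (is.character(predicted)) predicted <- parse_dotbracket(predicted)
  if (is.character(reference)) reference <- parse_dotbracket(reference)
  pc <- classify_pairs(predicted, reference, min_hairpin,
                       compatible_as_tn)
  ss <- sensitivity_specificity(pc)
  data.frame(TP = pc$TP, FP = pc$FP, FN = pc$FN, TN = pc$TN,
             compatible = pc$compatible, MCC = mcc(pc),
             sensitivity = ss[["sensitivity"]],
             specificity = ss[["specificity"]])
}
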
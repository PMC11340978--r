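#' Ordinal grade encoding (cumulative "NNRank" targets)
#'
#' Stertor and BOAS grades are ordered categories 0 (none) < 1 (mild) <
#' 2 (moderate) < 3 (severe). Instead of a one-hot target, the cumulative
#' encoding sets position `i` (0-based) to 1 for every `i <= g`, so the
#' target for grade 2 is `[1, 1, 1, 0]`. Position 0 is therefore always 1
#' and carries no information; positions 1-3 are the binary events
#' "grade >= 1", "grade >= 2", "grade >= 3".
#'
#' @param g Integer grade in 0..3 (vectorised).
#' @return For scalar `g`, a length-4 0/1 vector; for vector `g`, a
#'   `[length(g) x 4]` matrix with one encoded row per grade.
#' @export
encode_grade <- function(g) {
  if (any(is.na(g)) || any(g != as.integer(g)) || any(g < 0 | g > 3)) {
    stop("grade must be an integer in 0..3")
  }
  g <- as.integer(g)
  out <- t(vapply(g, function(gi) as.numeric(0:3 <= gi), numeric(4)))
  if (length(g) == 1L) out <- drop(out)
  out
}

#' Ordinal (per-position sigmoid) binary cross-entropy loss
#'
#' The network emits 4 logits per recording; each is squashed by a sigmoid
#' and compared with the corresponding cumulative target bit under binary
#' cross-entropy, averaged over the 4 positions. Computed in the numerically
#' stabilised logits form `max(l, 0) - l * y + log1p(exp(-|l|))`, which is
#' finite for arbitrarily large logits.
#'
#' @param logits Numeric vector of 4 logits, or an `[n x 4]` matrix.
#' @param target Length-4 cumulative 0/1 target (or `[n x 4]` matrix).
#' @return Mean binary cross-entropy (scalar).
#' @export
ordinal_loss <- function(logits, target) {
  logits <- as.numeric(logits)
  target <- as.numeric(target)
  stopifnot(length(logits) == length(target), all(is.finite(logits)))
  per <- pmax(logits, 0) - logits * target + log1p(exp(-abs(logits)))
  mean(per)
}

#' Decode ordinal outputs into a grade
#'
#' Applies the thresholding rule for cumulative ordinal outputs: the decoded
#' grade is the lowest category whose output falls below the threshold,
#' minus one; if no output falls below the threshold the grade is 3. Because
#' target position 0 is 1 for every class, an output vector whose first
#' entry is already below threshold decodes to grade 0 (the only consistent
#' completion of the rule). The raw output vector is used as-is; no
#' monotonising correction is applied.
#'
#' @param outputs Numeric vector of 4 probabilities in `[0, 1]`, or an
#'   `[n x 4]` matrix (decoded row-wise).
#' @param threshold Decoding threshold in (0, 1), default 0.5.
#' @return Integer grade(s) in 0..3.
#' @export
decode_outputs <- function(outputs, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.matrix(outputs)) {
    return(apply(outputs, 1L, decode_outputs, threshold = threshold))
  }
  stopifnot(length(outputs) == 4L, all(outputs >= 0 & outputs <= 1))
  below <- which(outputs < threshold)
  k <- if (length(below)) below[1L] - 1L else 4L   # count of leading >= tau
  max(min(k - 1L, 3L), 0L)
}

#' Continuous severity score from ordinal outputs
#'
#' Sum of outputs at positions 1-3 (0-based), i.e. the expected grade under
#' the cumulative reading `P(grade >= 1) + P(grade >= 2) + P(grade >= 3)`.
#' Position 0 is excluded because its target is identically 1. The score
#' lives on `[0, 3]` and supplies the continuous axis for ROC analysis.
#'
#' @param outputs Length-4 probability vector or `[n x 4]` matrix.
#' @return Severity score(s) in `[0, 3]`.
#' @export
severity_score <- function(outputs) {
  if (is.matrix(outputs)) {
    stopifnot(ncol(outputs) == 4L)
    return(rowSums(outputs[, 2:4, drop = FALSE]))
  }
  stopifnot(length(outputs) == 4L, all(outputs >= 0 & outputs <= 1))
  sum(outputs[2:4])
}
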
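#' Topological exposure class of a disease-drug-drug triple
#'
#' Classifies the unordered configuration of a query disease module and two
#' drug modules by the sign pattern of the two proximity z-scores and the
#' drug-drug separation. Class II, *Complementary Exposure* -- both drug
#' modules overlap the disease neighborhood (z < 0) while being mutually
#' separated -- is the configuration associated with synergy and the only
#' one rewarded by the localization score.
#'
#' The six classes:
#' \tabular{lll}{
#'   I   \tab both z < 0 \tab modules overlapping (not separated) \cr
#'   II  \tab both z < 0 \tab modules separated (Complementary Exposure) \cr
#'   III \tab one z < 0  \tab modules overlapping \cr
#'   IV  \tab one z < 0  \tab modules separated \cr
#'   V   \tab no z < 0   \tab modules overlapping \cr
#'   VI  \tab no z < 0   \tab modules separated
#' }
#'
#' @param z_QA,z_QB Proximity z-scores of the two drug modules to the query
#'   disease module.
#' @param s_AB Separation between the two drug modules.
#' @param separated_positive Convention switch for "separated": `TRUE`
#'   (default) treats `s_AB > 0` as separated, consistent with the
#'   separation measure's definition (positive s = topologically separated
#'   modules); `FALSE` flips the inequality.
#' @return Character vector of class labels `"I"` .. `"VI"` (vectorized over
#'   the inputs).
#' @export
classify_exposure <- function(z_QA, z_QB, s_AB, separated_positive = TRUE) {
  stopifnot(length(z_QA) == length(z_QB), length(z_QB) == length(s_AB))
  n_close <- (z_QA < 0) + (z_QB < 0)
  sep <- if (separated_positive) s_AB > 0 else s_AB < 0
  out <- character(length(s_AB))
  out[n_close == 2 & !sep] <- "I"
  out[n_close == 2 & sep]  <- "II"
  out[n_close == 1 & !sep] <- "III"
  out[n_close == 1 & sep]  <- "IV"
  out[n_close == 0 & !sep] <- "V"
  out[n_close == 0 & sep]  <- "VI"
  out
}

#' Localization score of an exposure class
#'
#' 2 for Complementary Exposure (class II), 0 for every other class.
#'
#' @param cls Character vector of class labels from [classify_exposure()].
#' @return Numeric vector of 0/2.
#' @export
t_score <- function(cls) ifelse(cls == "II", 2, 0)

#' Pair-level proximity score
#'
#' Mean of the two scaled proximities: `(P_QA + P_QB) / 2`.
#' @param P_QA,P_QB Scaled proximities in \[0, 1\] (see [scale_to_unit()]).
#' @export
p_score <- function(P_QA, P_QB) {
  stopifnot(all(P_QA >= 0 & P_QA <= 1), all(P_QB >= 0 & P_QB <= 1))
  (P_QA + P_QB) / 2
}

#' Pair-level transcriptional correlation score
#'
#' Mean of the absolute cosine correlations: `(|C_QA| + |C_QB|) / 2`.
#' @param C_QA,C_QB Cosine correlations in \[-1, 1\].
#' @export
c_score <- function(C_QA, C_QB) {
  stopifnot(all(abs(C_QA) <= 1, na.rm = TRUE), all(abs(C_QB) <= 1, na.rm = TRUE))
  (abs(C_QA) + abs(C_QB)) / 2
}

#' Combined prediction score
#'
#' `T + P + C`: localization (0 or 2) + mean scaled proximity (\[0, 1\]) +
#' mean absolute transcriptional correlation (\[0, 1\]); range \[0, 4\].
#' @param T_,P_,C_ Component scores.
#' @export
prediction_score <- function(T_, P_, C_) T_ + P_ + C_

#' Score and rank all drug pairs for a query disease
#'
#' Builds every unordered pair from per-drug statistics and a pairwise
#' separation lookup, computes the exposure class and the three score
#' components, and returns the table sorted by total score (descending; ties
#' broken by lexicographic drug names, so the ranking is independent of input
#' order). Pairs whose transcriptional correlation is undefined (`NA`, e.g.
#' insufficient module overlap) are scored with `C = 0` and flagged in the
#' `c_imputed` column rather than dropped.
#'
#' @param drug_stats `data.frame` with columns `drug`, `z` (proximity
#'   z-score), `P` (scaled proximity) and `C` (cosine correlation vs the
#'   query disease; may contain `NA`).
#' @param sep_matrix Symmetric numeric matrix of pairwise separations with
#'   drug names as dimnames (diagonal ignored).
#' @param separated_positive Passed to [classify_exposure()].
#' @return `data.frame` with one row per unordered pair, columns `drug_a`,
#'   `drug_b`, `z_qa`, `z_qb`, `s_ab`, `c_qa`, `c_qb`, `class`, `T`, `P`,
#'   `C`, `total`, `c_imputed`.
#' @export
rank_pairs <- function(drug_stats, sep_matrix, separated_positive = TRUE) {
  stopifnot(is.data.frame(drug_stats),
            all(c("drug", "z", "P", "C") %in% names(drug_stats)))
  drugs <- sort(as.character(drug_stats$drug))
  if (length(drugs) < 2L) stop("need at least two drugs", call. = FALSE)
  stats <- drug_stats[match(drugs, drug_stats$drug), ]
  idx <- utils::combn(length(drugs), 2L)
  ia <- idx[1L, ]; ib <- idx[2L, ]
  s_ab <- sep_matrix[cbind(match(drugs[ia], rownames(sep_matrix)),
                           match(drugs[ib], colnames(sep_matrix)))]
  c_qa <- stats$C[ia]; c_qb <- stats$C[ib]
  imputed <- is.na(c_qa) | is.na(c_qb)
  cls <- classify_exposure(stats$z[ia], stats$z[ib], s_ab,
                           separated_positive = separated_positive)
  T_ <- t_score(cls)
  P_ <- p_score(stats$P[ia], stats$P[ib])
  C_ <- c_score(ifelse(is.na(c_qa), 0, c_qa), ifelse(is.na(c_qb), 0, c_qb))
  out <- data.frame(drug_a = drugs[ia], drug_b = drugs[ib],
                    z_qa = stats$z[ia], z_qb = stats$z[ib], s_ab = s_ab,
                    c_qa = c_qa, c_qb = c_qb, class = cls,
                    T = T_, P = P_, C = C_,
                    total = prediction_score(T_, P_, C_),
                    c_imputed = imputed,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total, out$drug_a, out$drug_b, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' ROC AUC of a ranking against known positives
#'
#' Mann-Whitney form: the probability that a randomly chosen positive
#' outranks a randomly chosen negative, with ties counting one half.
#'
#' @param scores Numeric vector of scores (higher = ranked better).
#' @param positive Logical vector (same length) marking the known positives.
#' @return AUC in \[0, 1\].
#' @export
ranking_auc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive), is.logical(positive))
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L) stop("no positives", call. = FALSE)
  if (n_neg == 0L) stop("no negatives", call. = FALSE)
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Label pairs in a ranked table as known synergistic
#'
#' @param pairs A ranked pair table ([rank_pairs()] output).
#' @param positives `data.frame` with columns `drug_a`, `drug_b` (order
#'   within a pair is ignored).
#' @return Logical vector over the rows of `pairs`.
#' @export
match_known_pairs <- function(pairs, positives) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  key(pairs$drug_a, pairs$drug_b) %in%
    key(as.character(positives$drug_a), as.character(positives$drug_b))
}
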
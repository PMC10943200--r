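#' Beam-probability confidence score
#'
#' The confidence (dominance) of the top-ranked beam hypothesis: its
#' probability divided by the total probability of the `N` hypotheses alive
#' at the end of the beam search,
#' `Confidence(i) = Prob(i) / sum_j Prob(j)`. With the default beam of
#' `N = 4`, four equal hypotheses give 0.25, and a top hypothesis
#' dominating the beam approaches 1.
#'
#' The computation is carried out on log-probabilities with a max-shift, so
#' beams whose raw probabilities underflow are handled exactly; the score
#' is invariant to adding any constant to all log-probabilities.
#'
#' @param beam a `beam_result` from [beam_search()], or a numeric vector of
#'   log-probabilities (use `log = FALSE` to pass plain probabilities).
#' @param log when `beam` is numeric, whether values are log-probabilities
#'   (default `TRUE`).
#' @return Confidence of the top (highest-probability) hypothesis, a
#'   fraction in `(0, 1]`.
#' @examples
#' confidence_score(c(0.4, 0.3, 0.2, 0.1), log = FALSE) # 0.4
#' @export
confidence_score <- function(beam, log = TRUE) {
  lp <- if (inherits(beam, "beam_result")) beam$logprobs else {
    if (!log) {
      if (any(beam <= 0)) abort("Probabilities must be positive.")
      base::log(beam)
    } else {
      beam
    }
  }
  if (length(lp) == 0L) abort("Empty beam: no hypotheses to score.")
  if (anyNA(lp) | any(lp == Inf)) abort("Invalid log-probabilities.")
  top <- max(lp)
  exp(top - logsumexp(lp))
}

#' Classify scores into the high / moderate / low bands
#'
#' Bands used for confidence-versus-accuracy summaries: high `[0.8, 1.0]`,
#' moderate `[0.5, 0.8)`, low `[0, 0.5)`.
#'
#' @param score numeric vector of average embedding scores.
#' @return factor with levels `low`, `moderate`, `high`.
#' @export
score_class <- function(score) {
  cut(score, breaks = c(-Inf, 0.5, 0.8, Inf),
      labels = c("low", "moderate", "high"), right = FALSE)
}
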
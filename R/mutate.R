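pam250_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("PAM250", package = "Biostrings", envir = e)
      cache <<- e$PAM250[STANDARD_AA, STANDARD_AA]
    }
    cache
  }
})

#' Mutate loop residues under a substitution matrix
#'
#' Substitutes a fraction of the residues at turn/loop positions (labels
#' \code{"L"}), leaving every strand residue untouched. Mutation sites are
#' sampled without replacement; the replacement residue is drawn with
#' probability proportional to the substitution-score odds
#' \eqn{10^{score/10}} of the PAM250 row of the original residue,
#' excluding the identity. Used to probe the stability of predicted folds
#' against loop divergence.
#'
#' @param labeled A [labeled_structure()].
#' @param rate Fraction of the whole sequence to mutate, in [0, 1]; the
#'   number of mutated positions is floor(rate * N).
#' @param substitution_table Optional 20x20 score matrix with standard
#'   one-letter dimnames; defaults to PAM250.
#' @param seed Integer seed; the same seed reproduces the same mutant.
#' @return A [protein_sequence()] with id suffixed \code{"_mut"}.
#' @export
mutate_loops <- function(labeled, rate = 0.05, substitution_table = NULL,
                         seed = 1L) {
  stopifnot(inherits(labeled, "labeled_structure"), rate >= 0, rate <= 1)
  mat <- if (is.null(substitution_table)) pam250_matrix()
    else substitution_table
  res <- labeled$sequence$residues
  loops <- which(labeled$states == "L" & res %in% STANDARD_AA)
  m <- floor(rate * labeled$sequence$N)
  if (m > length(loops)) {
    warning("only ", length(loops), " mutable loop positions for ", m,
            " requested mutations; mutating all of them")
    m <- length(loops)
  }
  set.seed(seed)
  if (m > 0L) {
    sites <- sort(sample(loops, m))
    for (pos in sites) {
      from <- res[pos]
      others <- setdiff(STANDARD_AA, from)
      wts <- 10^(mat[from, others] / 10)
      res[pos] <- sample(others, 1L, prob = wts)
    }
  }
  protein_sequence(paste0(labeled$sequence$id, "_mut"),
                   paste(res, collapse = ""))
}
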
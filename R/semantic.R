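#' Treat a corpus as a state trajectory
#'
#' Each word is a state and the token stream is the trajectory; document
#' boundaries become segment breaks, so discounted counting in
#' [sr_empirical()] never crosses a document.
#'
#' @param bundle A `corpus_bundle`.
#' @return A `dsi_trajectory` over `length(bundle$vocabulary)` states.
#' @export
corpus_to_trajectory <- function(bundle) {
  stopifnot(inherits(bundle, "corpus_bundle"))
  if (length(bundle$tokens) == 0) abort("empty token stream.")
  new_trajectory(bundle$tokens, breaks = bundle$doc_breaks,
                 n_states = length(bundle$vocabulary))
}

#' Train an embedding on a corpus
#'
#' Convenience pipeline: corpus -> empirical SR (document-windowed) ->
#' occupancy -> PSI -> factorization, with the word labels attached.
#'
#' @param bundle A `corpus_bundle`.
#' @param gamma Word discount (default 0.9).
#' @param config A [dsi_config()]; when omitted, word defaults are derived:
#'   `D = min(300, floor(vocab / 4))`, a smaller step (`0.02`) than the
#'   spatial default (small vocabularies destabilize larger steps) and the
#'   word-scale L1 weight `0.1` for the sparse variant.
#' @return A `dsi_embedding` with word labels.
#' @export
train_word_embedding <- function(bundle, gamma = 0.9, config = NULL) {
  if (is.null(config)) {
    v <- length(bundle$vocabulary)
    config <- dsi_config(D = max(2L, min(300L, v %/% 4L)),
                         learning_rate = 0.02, rho_l1 = 0.1)
  }
  traj <- corpus_to_trajectory(bundle)
  sr <- sr_empirical(traj, gamma)
  p <- occupancy(traj)
  psi <- compute_psi(sr, p)
  dsi_factorize(psi, config, labels = bundle$vocabulary)
}

#' Words most activating one unit
#'
#' @param embedding A `dsi_embedding` with word labels.
#' @param unit Unit (column) index.
#' @param k How many words (default 10). Truncated with a warning if larger
#'   than the vocabulary.
#' @return Character vector of words, descending by activation; ties broken
#'   by vocabulary order.
#' @export
top_words <- function(embedding, unit, k = 10) {
  stopifnot(unit >= 1, unit <= ncol(embedding$X))
  v <- embedding$X[, unit]
  if (k > length(v)) {
    warn("k exceeds the vocabulary size; truncating.")
    k <- length(v)
  }
  embedding$labels[order(-v)[seq_len(k)]]
}

#' Binary / hierarchical category similarity oracle
#'
#' A ground-truth stand-in for lexical similarity on synthetic corpora:
#' words in the same category score `within`; with a supercategory map,
#' words in sibling categories score `related`; otherwise 0.
#'
#' @param categories Named character vector, word -> category.
#' @param supercategories Optional named character vector,
#'   category -> supercategory.
#' @param within,related Scores (defaults 1 and 0.25).
#' @return A `function(word1, word2)` returning a similarity.
#' @export
category_similarity_oracle <- function(categories, supercategories = NULL,
                                       within = 1, related = 0.25) {
  force(categories); force(supercategories)
  function(w1, w2) {
    c1 <- categories[[w1]]
    c2 <- categories[[w2]]
    if (identical(c1, c2)) return(within)
    if (!is.null(supercategories)) {
      s1 <- supercategories[c1][[1]] %||% NA_character_
      s2 <- supercategories[c2][[1]] %||% NA_character_
      if (!is.na(s1) && !is.na(s2) && s1 == s2) return(related)
    }
    0
  }
}

#' Conceptual specificity of embedding units
#'
#' For every unit, the mean pairwise similarity of its TOP-`k` words
#' (`choose(k, 2)` pairs) is compared against a null distribution of
#' `n_null` random word-pair similarities. A unit is a significant
#' concept-specific unit if its mean exceeds the null's 95th percentile;
#' its specificity is `s_unit / s_null - 1` with `s_null` the null mean.
#'
#' @param embedding A `dsi_embedding` with word labels.
#' @param similarity_fn Injected `function(word1, word2) -> similarity`
#'   (e.g. [category_similarity_oracle()] or a lexical-database adapter).
#' @param n_null Random pairs in the null (default 1000).
#' @param seed Integer seed for the null sampling.
#' @param k TOP-word count per unit (default 10).
#' @return A tibble with one row per unit: `unit`, `s_unit`, `significant`,
#'   `specificity`, and `top` (list column of the TOP-k words). Attributes
#'   `s_null`, `threshold`, `fraction_significant`, `mean_specificity`.
#'   Specificity is `NA` (flagged by a warning) if `s_null` is 0.
#' @export
conceptual_specificity <- function(embedding, similarity_fn, n_null = 1000,
                                   seed = 1, k = 10) {
  vocab <- embedding$labels
  if (length(vocab) < 2) abort("need at least 2 vocabulary words.")
  null_sims <- withr::with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      pr <- sample.int(length(vocab), 2)
      similarity_fn(vocab[pr[1]], vocab[pr[2]])
    }, numeric(1))
  })
  s_null <- mean(null_sims)
  threshold <- quantile(null_sims, 0.95, names = FALSE)
  if (s_null == 0) warn("null mean similarity is 0; specificity undefined.")

  D <- ncol(embedding$X)
  tops <- vector("list", D)
  s_unit <- rep(NA_real_, D)
  for (u in seq_len(D)) {
    tw <- top_words(embedding, u, k)
    # only words the unit actually activates belong to its tuning profile:
    # truncate the TOP list at zero activation (sparse units may activate
    # fewer than k words); fewer than 2 leaves the similarity undefined
    act <- embedding$X[match(tw, embedding$labels), u]
    tw <- tw[act > 0]
    tops[[u]] <- tw
    if (length(tw) < 2) next
    pairs <- utils::combn(tw, 2)
    s_unit[u] <- mean(vapply(seq_len(ncol(pairs)), function(j) {
      similarity_fn(pairs[1, j], pairs[2, j])
    }, numeric(1)))
  }
  significant <- !is.na(s_unit) & s_unit > threshold
  specificity <- if (s_null > 0) s_unit / s_null - 1 else rep(NA_real_, D)
  # dead units carry NA specificity and are never significant
  out <- tibble::tibble(unit = seq_len(D), s_unit = s_unit,
                        significant = significant,
                        specificity = specificity, top = tops)
  attr(out, "s_null") <- s_null
  attr(out, "threshold") <- threshold
  attr(out, "fraction_significant") <- mean(significant)
  attr(out, "mean_specificity") <- mean(specificity, na.rm = TRUE)
  out
}

#' Population-level similarity of word pairs
#'
#' Cosine similarity (or `1 - Pearson` dissimilarity) between the state
#' vectors of word pairs; given reference scores, also their Spearman rank
#' correlation with the computed similarities.
#'
#' @param embedding A `dsi_embedding` with word labels.
#' @param word_pairs Data frame with columns `word1`, `word2` and
#'   optionally `score` (reference similarity).
#' @param metric `"cosine"` (default) or `"pearson_dissimilarity"`.
#' @return The input tibble with a `similarity` column (NA, with a warning,
#'   for all-zero vectors); attribute `spearman` when reference scores are
#'   present.
#' @export
population_similarity <- function(embedding, word_pairs,
                                  metric = c("cosine", "pearson_dissimilarity")) {
  metric <- match.arg(metric)
  wp <- tibble::as_tibble(word_pairs)
  idx1 <- match(wp$word1, embedding$labels)
  idx2 <- match(wp$word2, embedding$labels)
  if (anyNA(idx1) || anyNA(idx2)) abort("word pair member out of vocabulary.")
  sims <- vapply(seq_len(nrow(wp)), function(i) {
    a <- embedding$X[idx1[i], ]
    b <- embedding$X[idx2[i], ]
    if (metric == "cosine") {
      .cosine(a, b)
    } else {
      if (sd(a) == 0 || sd(b) == 0) NA_real_ else 1 - cor(a, b)
    }
  }, numeric(1))
  if (anyNA(sims)) warn("undefined similarity for degenerate vectors (flagged NA).")
  wp$similarity <- sims
  if ("score" %in% names(wp)) {
    attr(wp, "spearman") <- cor(wp$score, wp$similarity, method = "spearman",
                                use = "complete.obs")
  }
  wp
}

# Build the analogy query vector x(c) + x(b) - x(a), optionally restricted
# to the k_dims/2 largest and k_dims/2 smallest dimensions of x(b) - x(a)
# (max side favored when odd); clipped at zero.
.analogy_query <- function(embedding, ia, ib, ic, k_dims) {
  diff <- embedding$X[ib, ] - embedding$X[ia, ]
  q <- embedding$X[ic, ]
  D <- length(diff)
  if (is.null(k_dims) || k_dims >= D) {
    q <- q + diff
  } else {
    n_max <- ceiling(k_dims / 2)
    n_min <- k_dims - n_max
    ord <- order(diff)
    dims <- c(head(ord, n_min), tail(ord, n_max))
    q[dims] <- q[dims] + diff[dims]
  }
  pmax(q, 0)
}

#' Analogical inference by vector arithmetic
#'
#' Answers `a : b :: c : ?` with the query `x(c) + x(b) - x(a)` (clipped at
#' zero), ranking all other words by cosine similarity. With `k_dims`, only
#' the `k_dims / 2` maximum and `k_dims / 2` minimum dimensions of
#' `x(b) - x(a)` are added to `x(c)` -- the partial-recombination variant
#' that switches a few concept units on and off.
#'
#' @param embedding A `dsi_embedding` with word labels.
#' @param a,b,c Words (in vocabulary).
#' @param k_dims `NULL` for the full vector, or the number of dimensions to
#'   recombine (<= D).
#' @return Tibble `word`, `similarity`, ranked descending, excluding `a`,
#'   `b`, `c`; the top row is the inferred answer.
#' @export
analogy <- function(embedding, a, b, c, k_dims = NULL) {
  idx <- match(c(a, b, c), embedding$labels)
  if (anyNA(idx)) abort("analogy member out of vocabulary.")
  D <- ncol(embedding$X)
  if (!is.null(k_dims)) {
    stopifnot(k_dims >= 1)
    if (k_dims > D) abort("`k_dims` exceeds the embedding dimensionality.")
  }
  q <- .analogy_query(embedding, idx[1], idx[2], idx[3], k_dims)
  sims <- .cosine_rows(embedding$X, q)
  keep <- setdiff(seq_len(nrow(embedding$X)), idx)
  out <- tibble::tibble(word = embedding$labels[keep],
                        similarity = sims[keep])
  dplyr::arrange(out, dplyr::desc(.data$similarity))
}

#' Share of the largest element in each state/word vector
#'
#' How concentrated each row of `X` is: the largest entry divided by the
#' row sum. Distributed codes sit well below 1 (each item is a blend of
#' many units); one-hot codes sit at 1.
#'
#' @param embedding A `dsi_embedding`.
#' @return Tibble `label`, `share` (`NA` for all-zero rows).
#' @export
largest_element_share <- function(embedding) {
  rs <- rowSums(abs(embedding$X))
  share <- ifelse(rs > 0, apply(abs(embedding$X), 1, max) / rs, NA_real_)
  tibble::tibble(label = embedding$labels, share = unname(share))
}

#' Accuracy on a set of analogy quadruples
#'
#' @param embedding A `dsi_embedding` with word labels.
#' @param quadruples Data frame with columns `a`, `b`, `c`, `d`.
#' @param k_dims Passed to [analogy()].
#' @return Fraction of quadruples whose top-1 answer equals `d`.
#' @export
analogy_accuracy <- function(embedding, quadruples, k_dims = NULL) {
  correct <- vapply(seq_len(nrow(quadruples)), function(i) {
    res <- analogy(embedding, quadruples$a[i], quadruples$b[i],
                   quadruples$c[i], k_dims = k_dims)
    identical(res$word[1], quadruples$d[i])
  }, logical(1))
  mean(correct)
}
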
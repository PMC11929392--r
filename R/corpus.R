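#' Specification for synthetic corpora
#'
#' Parameters of the planted-structure token-stream generators. The default
#' sizes (10 categories of 10 words, 200k tokens) mirror the
#' ten-categories-of-ten-words design used for population-level semantic
#' analyses, at a scale where embeddings train in seconds.
#'
#' @param n_categories Number of semantic categories (categorical corpus).
#' @param words_per_category Words per category.
#' @param n_families Number of relational families (relational corpus),
#'   e.g. country-capital.
#' @param pairs_per_family Entity pairs per family.
#' @param doc_length Tokens per document.
#' @param n_docs Number of documents.
#' @param boost Within-topic probability boost (> 1 for planted structure;
#'   `Inf` makes documents purely within-topic).
#' @param n_background High-frequency topic-free words (function-word
#'   analogue; default 0). They co-occur with everything, so factorization
#'   methods must separate them from the categorical structure, and each
#'   carries its own singleton ground-truth label.
#' @param background_weight Sampling weight of each background word
#'   relative to an inactive category word (default 5).
#' @param seed Integer seed.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_categories = 10, words_per_category = 10,
                        n_families = 2, pairs_per_family = 5,
                        doc_length = 100, n_docs = 2000,
                        boost = 5, n_background = 0,
                        background_weight = 5, seed = 1) {
  stopifnot(n_categories >= 1, words_per_category >= 1, n_families >= 1,
            pairs_per_family >= 1, doc_length >= 1, n_docs >= 1,
            n_background >= 0, background_weight > 0)
  if (boost <= 1) abort("`boost` must exceed 1 for planted structure to exist.")
  structure(list(n_categories = n_categories,
                 words_per_category = words_per_category,
                 n_families = n_families,
                 pairs_per_family = pairs_per_family,
                 doc_length = doc_length, n_docs = n_docs,
                 boost = boost, n_background = n_background,
                 background_weight = background_weight,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Construct a corpus bundle
#'
#' @param tokens Integer vector of vocabulary indices.
#' @param vocabulary Character vector of word strings.
#' @param doc_breaks 1-based token positions where documents begin.
#' @param categories Optional named character vector (word -> category).
#' @param quadruples Optional tibble of analogy quadruples `a`, `b`, `c`,
#'   `d` with `a:b :: c:d`.
#' @return A `corpus_bundle`.
#' @export
corpus_bundle <- function(tokens, vocabulary, doc_breaks = 1L,
                          categories = NULL, quadruples = NULL) {
  tokens <- as.integer(tokens)
  if (any(tokens < 1) || any(tokens > length(vocabulary))) {
    abort("token indexes the vocabulary out of range.")
  }
  if (!is.null(quadruples)) {
    quadwords <- unlist(quadruples[, c("a", "b", "c", "d")], use.names = FALSE)
    if (!all(quadwords %in% vocabulary)) abort("quadruple member out of vocabulary.")
  }
  structure(list(tokens = tokens, vocabulary = vocabulary,
                 doc_breaks = as.integer(doc_breaks),
                 categories = categories, quadruples = quadruples),
            class = "corpus_bundle")
}

#' @export
print.corpus_bundle <- function(x, ...) {
  cat(sprintf("<corpus_bundle> %d tokens, %d words, %d documents\n",
              length(x$tokens), length(x$vocabulary), length(x$doc_breaks)))
  invisible(x)
}

#' Generate a token stream with planted categorical structure
#'
#' Documents are drawn from a mixture process: each document activates a
#' small number of categories (one or two) and samples tokens with
#' probability mass boosted on the active categories' words. Within-category
#' co-occurrence therefore exceeds between-category co-occurrence by
#' construction, with contrast controlled by `boost`.
#'
#' @param spec A [corpus_spec()].
#' @return A `corpus_bundle` with ground-truth category labels. Warns (and
#'   plants no contrast) for a single-category spec.
#' @export
generate_categorical_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  if (spec$n_categories == 1) {
    warn("single category: no planted categorical contrast.")
  }
  vocab <- as.vector(outer(
    sprintf("w%02d", seq_len(spec$words_per_category)),
    sprintf("cat%02d", seq_len(spec$n_categories)),
    function(w, c) paste0(c, "_", w)))
  word_cat <- rep(sprintf("cat%02d", seq_len(spec$n_categories)),
                  each = spec$words_per_category)
  if (spec$n_background > 0) {
    bg <- sprintf("bg%03d", seq_len(spec$n_background))
    vocab <- c(vocab, bg)
    word_cat <- c(word_cat, bg)   # singleton labels: no two bg words match
  }
  names(word_cat) <- vocab
  V <- length(vocab)
  is_bg <- startsWith(vocab, "bg")

  withr::with_seed(spec$seed, {
    tokens <- integer(spec$n_docs * spec$doc_length)
    breaks <- seq(1L, by = spec$doc_length, length.out = spec$n_docs)
    for (d in seq_len(spec$n_docs)) {
      k <- sample(1:2, 1)
      active <- sample.int(spec$n_categories, min(k, spec$n_categories))
      wts <- rep(1, V)
      wts[is_bg] <- spec$background_weight
      in_active <- word_cat %in% sprintf("cat%02d", active)
      if (is.infinite(spec$boost)) {
        wts[!in_active & !is_bg] <- 0
      } else {
        wts[in_active] <- spec$boost
      }
      tokens[breaks[d] + 0:(spec$doc_length - 1)] <-
        sample.int(V, spec$doc_length, replace = TRUE, prob = wts)
    }
    corpus_bundle(tokens, vocab, breaks, categories = word_cat)
  })
}

# All consistent analogy quadruples of a relational vocabulary: within each
# family, for ordered entity pairs e1 != e2, both role directions.
.relational_quadruples <- function(word_of) {
  out <- list()
  for (f in seq_len(dim(word_of)[1])) {
    ents <- seq_len(dim(word_of)[3])
    for (e1 in ents) for (e2 in ents) {
      if (e1 == e2) next
      out[[length(out) + 1]] <- tibble::tibble(
        a = word_of[f, 1, e1], b = word_of[f, 2, e1],
        c = word_of[f, 1, e2], d = word_of[f, 2, e2])
      out[[length(out) + 1]] <- tibble::tibble(
        a = word_of[f, 2, e1], b = word_of[f, 1, e1],
        c = word_of[f, 2, e2], d = word_of[f, 1, e2])
    }
  }
  dplyr::bind_rows(out)
}

#' Generate a token stream with planted relational structure
#'
#' Every word carries two latent factors: a role within a relational family
#' (e.g. country vs capital) and an entity identity (e.g. one
#' country-capital pair). Each document activates either one entity (its
#' two role words co-occur) or one family role (that role's words co-occur
#' across entities), so co-occurrence couples words sharing either factor.
#' All consistent analogy quadruples `(a, b, c, d)` -- same-family role
#' swaps across entity pairs, in both directions -- are emitted as ground
#' truth.
#'
#' @param spec A [corpus_spec()] with `n_families >= 2` and
#'   `pairs_per_family >= 2`.
#' @return A `corpus_bundle` with `quadruples` and per-word factor labels in
#'   `categories` (role as category).
#' @export
generate_relational_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  if (spec$n_families < 2 || spec$pairs_per_family < 2) {
    abort("need >= 2 relational families and >= 2 pairs per family.")
  }
  F <- spec$n_families
  P <- spec$pairs_per_family
  word_of <- array("", dim = c(F, 2, P))
  for (f in seq_len(F)) for (r in 1:2) for (e in seq_len(P)) {
    word_of[f, r, e] <- sprintf("f%dr%de%02d", f, r - 1, e)
  }
  vocab <- as.vector(aperm(word_of, c(3, 2, 1)))
  role_of <- setNames(rep("", length(vocab)), vocab)
  for (f in seq_len(F)) for (r in 1:2) for (e in seq_len(P)) {
    role_of[word_of[f, r, e]] <- sprintf("f%dr%d", f, r - 1)
  }
  V <- length(vocab)
  quads <- .relational_quadruples(word_of)

  withr::with_seed(spec$seed, {
    tokens <- integer(spec$n_docs * spec$doc_length)
    breaks <- seq(1L, by = spec$doc_length, length.out = spec$n_docs)
    for (d in seq_len(spec$n_docs)) {
      f <- sample.int(F, 1)
      wts <- rep(1, V)
      if (runif(1) < 0.5) {
        e <- sample.int(P, 1)   # entity document: both roles of one entity
        active <- c(word_of[f, 1, e], word_of[f, 2, e])
      } else {
        r <- sample.int(2, 1)   # role document: one role across entities
        active <- word_of[f, r, ]
      }
      idx <- match(active, vocab)
      if (is.infinite(spec$boost)) {
        wts[-idx] <- 0
      } else {
        wts[idx] <- spec$boost * V / length(idx)
      }
      tokens[breaks[d] + 0:(spec$doc_length - 1)] <-
        sample.int(V, spec$doc_length, replace = TRUE, prob = wts)
    }
    corpus_bundle(tokens, vocab, breaks, categories = role_of,
                  quadruples = quads)
  })
}

#' Write / read a corpus as plain text
#'
#' One document per line, whitespace-separated tokens. Ground truth travels
#' in sidecar files: `<path>.categories.csv` (word, category) and
#' `<path>.quadruples.txt` (four words per line) when present.
#'
#' @param bundle A `corpus_bundle`.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(bundle, path) {
  ends <- c(bundle$doc_breaks[-1] - 1L, length(bundle$tokens))
  lines <- vapply(seq_along(bundle$doc_breaks), function(d) {
    paste(bundle$vocabulary[bundle$tokens[bundle$doc_breaks[d]:ends[d]]],
          collapse = " ")
  }, character(1))
  writeLines(lines, path)
  if (!is.null(bundle$categories)) {
    utils::write.csv(
      data.frame(word = names(bundle$categories),
                 category = unname(bundle$categories)),
      paste0(path, ".categories.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$quadruples)) {
    writeLines(apply(bundle$quadruples[, c("a", "b", "c", "d")], 1, paste,
                     collapse = " "),
               paste0(path, ".quadruples.txt"))
  }
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) abort("empty document list.")
  docs <- strsplit(lines, "\\s+")
  docs <- lapply(docs, function(d) d[nzchar(d)])
  vocab <- sort(unique(unlist(docs)))
  tokens <- match(unlist(docs), vocab)
  breaks <- cumsum(c(1L, head(lengths(docs), -1)))
  categories <- NULL
  catfile <- paste0(path, ".categories.csv")
  if (file.exists(catfile)) {
    df <- utils::read.csv(catfile)
    categories <- setNames(as.character(df$category), df$word)
  }
  quadruples <- NULL
  quadfile <- paste0(path, ".quadruples.txt")
  if (file.exists(quadfile)) {
    qm <- do.call(rbind, strsplit(readLines(quadfile), "\\s+"))
    quadruples <- tibble::tibble(a = qm[, 1], b = qm[, 2],
                                 c = qm[, 3], d = qm[, 4])
  }
  corpus_bundle(tokens, vocab, breaks, categories = categories,
                quadruples = quadruples)
}
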
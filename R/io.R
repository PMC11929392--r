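#' Write / read an embedding matrix in word2vec-style text format
#'
#' Header line `"N D"`, then one line per row: `label v1 ... vD`,
#' whitespace-separated, values printed with 17 significant digits so a
#' write-read-write cycle reproduces the file byte for byte.
#'
#' @param mat Numeric matrix (rows = states/words).
#' @param labels Row labels (state indices or word strings).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_embedding_matrix <- function(mat, labels, path) {
  stopifnot(length(labels) == nrow(mat))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(mat), ncol(mat)), con)
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(labels[i], paste(sprintf("%.17g", mat[i, ]), collapse = " "))
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_embedding_matrix
#' @export
read_embedding_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2 || anyNA(suppressWarnings(as.integer(hdr)))) {
    abort("malformed header at line 1: expected \"N D\".")
  }
  n <- as.integer(hdr[1]); d <- as.integer(hdr[2])
  if (length(lines) - 1 != n) {
    abort(sprintf("header declares %d rows but file has %d.", n,
                  length(lines) - 1))
  }
  labels <- character(n)
  mat <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(parts) != d + 1) {
      abort(sprintf("line %d has %d fields; expected label + %d values.",
                    i + 1, length(parts), d))
    }
    labels[i] <- parts[1]
    mat[i, ] <- as.numeric(parts[-1])
  }
  rownames(mat) <- labels
  mat
}

#' Persist / restore a fitted embedding
#'
#' Writes `<prefix>_X.txt` and `<prefix>_W.txt` (word2vec-style text,
#' [write_embedding_matrix()]) plus `<prefix>.yml` with the variant and the
#' config snapshot.
#'
#' @param embedding A `dsi_embedding`.
#' @param prefix File prefix (directories must exist).
#' @return `prefix`, invisibly.
#' @export
save_dsi <- function(embedding, prefix) {
  write_embedding_matrix(embedding$X, embedding$labels,
                         paste0(prefix, "_X.txt"))
  write_embedding_matrix(embedding$W, embedding$labels,
                         paste0(prefix, "_W.txt"))
  meta <- list(variant = embedding$variant,
               config = unclass(embedding$config),
               dead_reinits = embedding$dead_reinits)
  yaml::write_yaml(meta, paste0(prefix, ".yml"))
  invisible(prefix)
}

#' @rdname save_dsi
#' @export
load_dsi <- function(prefix) {
  X <- read_embedding_matrix(paste0(prefix, "_X.txt"))
  W <- read_embedding_matrix(paste0(prefix, "_W.txt"))
  meta <- yaml::read_yaml(paste0(prefix, ".yml"))
  emb <- as_dsi_embedding(X, W, variant = meta$variant,
                          labels = rownames(X))
  emb$config <- meta$config
  emb
}

#' Export / import a trajectory as plain text
#'
#' One state index per line; header comment carries the environment hash.
#'
#' @param trajectory A `dsi_trajectory`.
#' @param path Output file.
#' @return `path` invisibly (writer); a `dsi_trajectory` (reader).
#' @export
write_trajectory <- function(trajectory, path) {
  writeLines(c(sprintf("# env %s n_states %d",
                       trajectory$env_hash %||% "NA", trajectory$n_states),
               as.character(trajectory$states)), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\\s+")[[1]]
  n_states <- as.integer(hdr[5])
  new_trajectory(as.integer(lines[-1]), n_states = n_states,
                 env_hash = if (hdr[3] == "NA") NULL else hdr[3])
}

#' Environment configuration as key-value text
#'
#' @param env A [grid_env()].
#' @param path YAML file.
#' @return `path` invisibly (writer); a [grid_env()] (reader).
#' @export
write_env_config <- function(env, path) {
  cfg <- list(width = env$width, height = env$height)
  if (nrow(env$blocked) > 0) {
    cfg$blocked <- lapply(seq_len(nrow(env$blocked)),
                          function(i) as.list(env$blocked[i, ]))
  }
  if (!is.null(env$walls)) cfg$walls <- env$walls
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_env_config
#' @export
read_env_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("width", "height")) {
    if (is.null(cfg[[f]])) abort(sprintf("config is missing field `%s`.", f))
  }
  blocked <- if (!is.null(cfg$blocked)) {
    do.call(rbind, lapply(cfg$blocked, unlist))
  }
  grid_env(cfg$width, cfg$height, blocked = blocked, walls = cfg$walls)
}

.require_fields <- function(config, fields) {
  for (f in fields) {
    if (is.null(config[[f]])) abort(sprintf("config is missing field `%s`.", f))
  }
}

.experiment_env <- function(config) {
  spec <- config$env %||% list(width = 30, height = 30)
  if (is.character(spec)) {
    switch(spec,
           open = grid_env(30, 30),
           four_room = four_room_env(30),
           abort(sprintf("unknown env fixture `%s`.", spec)))
  } else {
    grid_env(spec$width, spec$height, blocked = spec$blocked,
             walls = spec$walls)
  }
}

.experiment_embedding <- function(env, config, seed) {
  cfg <- dsi_config(D = config$D %||% 100,
                    variant = config$variant %||% "decorr",
                    n_iter = config$n_iter %||% 3000,
                    seed = seed)
  list(embedding = train_spatial_embedding(
    env, cfg, gamma = config$gamma %||% 0.99,
    walk_length = config$walk_length %||% 200000, seed = seed,
    estimator = config$sr_estimator %||% "transition"))
}

#' Run a named experiment end-to-end
#'
#' Config-driven pipelines: `"space"` (walk -> SR -> PSI -> factorize ->
#' gridness), `"navigation"` (adds movement models, path integration and
#' navigation trials), `"context"` (trains barrier contexts, composes and
#' navigates the novel context), `"words"` (synthetic corpus -> embedding
#' -> conceptual specificity and analogies). Every run is determined by
#' `(config, seed)`; the config snapshot and a manifest of metrics are
#' written beside the outputs.
#'
#' @param config A list (or path to a YAML file) with at least `experiment`
#'   and `out_dir`; optional fields: `seed`, `gamma`, `D`, `variant`,
#'   `walk_length`, `n_iter`, `env` (fixture name `"open"`/`"four_room"` or
#'   a width/height/walls spec), `n_trials`, corpus fields (`corpus_type`,
#'   [corpus_spec()] arguments).
#' @return The manifest (named list of metrics), invisibly.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .require_fields(config, c("experiment", "out_dir"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  experiment <- config$experiment

  manifest <- list(experiment = experiment, seed = seed)
  if (experiment %in% c("space", "navigation")) {
    env <- .experiment_env(config)
    fit <- .experiment_embedding(env, config, seed)
    emb <- fit$embedding
    save_dsi(emb, file.path(out_dir, "embedding"))
    gridness <- classify_grid_units(emb, env,
                                    n_shuffles = config$n_shuffles %||% 100,
                                    seed = seed)
    utils::write.csv(gridness[, c("unit", "score", "threshold", "is_grid")],
                     file.path(out_dir, "gridness.csv"), row.names = FALSE)
    manifest$grid_fraction <- grid_fraction(gridness)
    manifest$final_loss <- emb$loss_trace[length(emb$loss_trace)]
    if (experiment == "navigation") {
      pi_rate <- path_integration_success_rate(
        emb, env, n_trials = config$n_trials %||% 1000, seed = seed)
      trials <- navigation_trials(emb, env,
                                  n_trials = config$n_trials %||% 1000,
                                  seed = seed)
      utils::write.csv(trials, file.path(out_dir, "navigation_trials.csv"),
                       row.names = FALSE)
      manifest$path_integration_successes <- pi_rate$successes
      manifest$mean_normalized_path_length <- mean(trials$normalized)
      manifest$reach_rate <- mean(trials$reached)
    }
  } else if (experiment == "context") {
    size <- config$size %||% 30
    envs <- barrier_context_envs(size)
    cfg <- dsi_config(D = config$D %||% 100,
                      variant = config$variant %||% "decorr",
                      n_iter = config$n_iter %||% 3000, seed = seed)
    ctx <- train_context_embeddings(
      envs, cfg, gamma = config$gamma %||% 0.99,
      walk_length = config$walk_length %||% 200000, seed = seed,
      finetune_iter = config$finetune_iter %||% 300)
    composed <- compose_context(ctx)
    save_dsi(composed, file.path(out_dir, "composed"))
    regions <- context_regions(envs$AB)
    trials <- navigation_trials(composed, envs$AB,
                                n_trials = config$n_trials %||% 1000,
                                seed = seed,
                                start_cells = regions$start,
                                goal_cells = regions$goal,
                                epsilon = config$epsilon %||% 0.1)
    utils::write.csv(trials, file.path(out_dir, "navigation_trials.csv"),
                     row.names = FALSE)
    manifest$mean_normalized_path_length <- mean(trials$normalized)
    manifest$reach_rate <- mean(trials$reached)
  } else if (experiment == "words") {
    spec_args <- config[intersect(names(config),
                                  names(formals(corpus_spec)))]
    spec_args$seed <- seed
    spec <- do.call(corpus_spec, spec_args)
    type <- config$corpus_type %||% "categorical"
    bundle <- if (type == "relational") {
      generate_relational_corpus(spec)
    } else {
      generate_categorical_corpus(spec)
    }
    write_corpus(bundle, file.path(out_dir, "corpus.txt"))
    cfg <- dsi_config(D = config$D %||% 30,
                      variant = config$variant %||% "decorr",
                      n_iter = config$n_iter %||% 500, seed = seed)
    emb <- train_word_embedding(bundle, gamma = config$gamma %||% 0.9,
                                config = cfg)
    save_dsi(emb, file.path(out_dir, "embedding"))
    if (!is.null(bundle$categories)) {
      oracle <- category_similarity_oracle(bundle$categories)
      spc <- conceptual_specificity(emb, oracle, seed = seed)
      manifest$fraction_significant <- attr(spc, "fraction_significant")
      manifest$mean_specificity <- attr(spc, "mean_specificity")
    }
    if (!is.null(bundle$quadruples)) {
      manifest$analogy_accuracy_full <-
        analogy_accuracy(emb, bundle$quadruples)
      manifest$analogy_accuracy_2dims <-
        analogy_accuracy(emb, bundle$quadruples, k_dims = 2)
    }
  } else {
    abort(sprintf("unknown experiment `%s`.", experiment))
  }

  yaml::write_yaml(config, file.path(out_dir, "config_snapshot.yml"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  invisible(manifest)
}
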
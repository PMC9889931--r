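#' Load a word-embedding space from a GloVe-format text file
#'
#' Reads the standard GloVe plain-text format: one record per line, a token
#' followed by `d` whitespace-separated floats. A leading header line holding
#' exactly two integer fields (vocabulary size and dimension, as written by
#' some embedding exporters) is detected and skipped. Duplicate tokens keep
#' their first occurrence; all-zero vectors are dropped because they have no
#' direction and break cosine computation. Both events emit a warning.
#'
#' @param path Path to the embedding file (UTF-8).
#' @param expected_dimension Optional integer; if supplied, loading fails
#'   unless the file's per-line float count equals it.
#' @return An `embedding_model`: a numeric matrix with one row per token
#'   (rownames are the tokens), plus `source_tag` attribute recording
#'   provenance.
#' @seealso [make_toy_embeddings()], [save_embeddings()], [embedding_lookup()]
#' @export
load_embeddings <- function(path, expected_dimension = NULL) {
  if (!file.exists(path)) {
    stop("embedding file not found: ", path)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty embedding file: ", path)
  }
  first <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1L]]
  skipped_header <- length(first) == 2L &&
    !anyNA(suppressWarnings(as.numeric(first))) &&
    all(grepl("^[0-9]+$", first))
  if (skipped_header) {
    lines <- lines[-1L]
    if (length(lines) == 0L) stop("empty embedding file (header only): ", path)
  }

  fields <- strsplit(trimws(lines), "[ \t]+")
  counts <- lengths(fields)
  if (length(unique(counts)) != 1L) {
    bad <- which(counts != counts[[1L]])[[1L]]
    stop("malformed embedding file: line ", bad + skipped_header,
         " has ", counts[[bad]], " fields but line ",
         1L + skipped_header, " has ", counts[[1L]])
  }
  d <- counts[[1L]] - 1L
  if (d < 1L) stop("malformed embedding file: no vector components found")
  if (!is.null(expected_dimension) && d != expected_dimension) {
    stop("embedding dimension mismatch: file has ", d,
         ", expected ", expected_dimension)
  }

  tokens <- vapply(fields, `[[`, character(1L), 1L)
  values <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[-1L]), numeric(d))
  )
  mat <- if (d == 1L) matrix(values, ncol = 1L) else t(values)
  if (anyNA(mat) || any(!is.finite(mat))) {
    bad <- which(apply(!is.finite(mat), 1L, any))[[1L]]
    stop("malformed embedding file: non-numeric or non-finite value on line ",
         bad + skipped_header)
  }

  dup <- duplicated(tokens)
  if (any(dup)) {
    warning(sum(dup), " duplicate token(s) in ", path,
            "; keeping first occurrence")
    mat <- mat[!dup, , drop = FALSE]
    tokens <- tokens[!dup]
  }
  zero <- rowSums(mat != 0) == 0L
  if (any(zero)) {
    warning("dropping ", sum(zero), " all-zero vector(s) in ", path)
    mat <- mat[!zero, , drop = FALSE]
    tokens <- tokens[!zero]
  }
  if (nrow(mat) == 0L) stop("empty embedding model after dropping zero vectors")
  rownames(mat) <- tokens
  new_embedding_model(mat, source_tag = path)
}

new_embedding_model <- function(mat, source_tag) {
  stopifnot(is.matrix(mat), is.numeric(mat), !is.null(rownames(mat)))
  structure(mat, source_tag = source_tag, class = c("embedding_model", "matrix"))
}

#' @export
print.embedding_model <- function(x, ...) {
  cat("<embedding_model> ", nrow(x), " tokens, dimension ", ncol(x),
      "\n  source: ", attr(x, "source_tag"), "\n", sep = "")
  invisible(x)
}

#' Look up one token's vector
#'
#' Lookup lower-cases the query first (GloVe distributions are mostly
#' lower-case and DT responses are free text) and falls back to the raw form.
#'
#' @param model An `embedding_model`.
#' @param token Character scalar.
#' @return Numeric vector of length `ncol(model)`, or `NULL` if the token is
#'   out of vocabulary.
#' @export
embedding_lookup <- function(model, token) {
  lowered <- tolower(token)
  if (lowered %in% rownames(model)) return(model[lowered, ])
  if (token %in% rownames(model)) return(model[token, ])
  NULL
}

#' Write an embedding model in GloVe text format
#'
#' Inverse of [load_embeddings()]: load -> save -> load is vector-wise
#' idempotent (up to the printed precision, 17 significant digits, which
#' round-trips IEEE doubles exactly).
#'
#' @param model An `embedding_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_embeddings <- function(model, path) {
  rows <- vapply(seq_len(nrow(model)), function(i) {
    paste(rownames(model)[i],
          paste(format(model[i, ], digits = 17, scientific = FALSE,
                       trim = TRUE),
                collapse = " "))
  }, character(1L))
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Configuration for the planted-cluster toy embedding generator
#'
#' @param n_clusters Number of planted semantic categories (>= 1).
#' @param tokens_per_cluster Tokens generated per category (>= 1).
#' @param dimension Embedding dimension (>= 2).
#' @param within_cluster_spread Noise scale in (0, 1): 0 collapses every
#'   token onto its centroid, values near 1 blur the categories.
#' @param seed Integer seed; identical configs generate identical models.
#' @return A `toy_embedding_config` list.
#' @export
toy_embedding_config <- function(n_clusters, tokens_per_cluster,
                                 dimension = 50L,
                                 within_cluster_spread = 0.1,
                                 seed = 1L) {
  if (n_clusters < 1L) stop("n_clusters must be >= 1")
  if (tokens_per_cluster < 1L) stop("tokens_per_cluster must be >= 1")
  if (dimension < 2L) stop("dimension must be >= 2")
  if (!is.finite(within_cluster_spread) ||
      within_cluster_spread <= 0 || within_cluster_spread >= 1) {
    stop("within_cluster_spread must lie in (0, 1)")
  }
  structure(list(n_clusters = as.integer(n_clusters),
                 tokens_per_cluster = as.integer(tokens_per_cluster),
                 dimension = as.integer(dimension),
                 within_cluster_spread = within_cluster_spread,
                 seed = as.integer(seed)),
            class = "toy_embedding_config")
}

#' Generate a synthetic embedding space with planted clusters
#'
#' Cluster centroids are unit vectors; when `n_clusters <= dimension` they
#' form a random orthonormal frame, so between-cluster centroid cosine
#' similarity is exactly 0 and within-cluster similarity exceeds it for any
#' spread below 1. Each token is its centroid plus isotropic Gaussian noise
#' of scale `within_cluster_spread`, renormalized to unit length. Tokens are
#' named `c{cluster}_t{index}`.
#'
#' @param config A [toy_embedding_config()].
#' @return An `embedding_model` with
#'   `n_clusters * tokens_per_cluster` unit-norm rows and a `clusters`
#'   attribute mapping each token to its planted cluster.
#' @export
make_toy_embeddings <- function(config) {
  stopifnot(inherits(config, "toy_embedding_config"))
  k <- config$n_clusters
  m <- config$tokens_per_cluster
  d <- config$dimension

  gen <- with_seed(config$seed, {
    if (k <= d) {
      centroids <- t(qr.Q(qr(matrix(stats::rnorm(k * d), nrow = d, ncol = k))))
    } else {
      centroids <- matrix(stats::rnorm(k * d), nrow = k, ncol = d)
      centroids <- centroids / sqrt(rowSums(centroids^2))
    }
    spread <- config$within_cluster_spread
    mat <- matrix(0, nrow = k * m, ncol = d)
    names_out <- character(k * m)
    for (ci in seq_len(k)) {
      noise <- matrix(stats::rnorm(m * d), nrow = m, ncol = d) * (spread / sqrt(d))
      vecs <- sweep(noise, 2L, centroids[ci, ], `+`)
      vecs <- vecs / sqrt(rowSums(vecs^2))
      idx <- (ci - 1L) * m + seq_len(m)
      mat[idx, ] <- vecs
      names_out[idx] <- sprintf("c%d_t%d", ci, seq_len(m))
    }
    rownames(mat) <- names_out
    mat
  })
  mat <- gen
  model <- new_embedding_model(
    mat, source_tag = sprintf("toy(k=%d,m=%d,d=%d,spread=%g,seed=%d)",
                              k, m, d, spread, config$seed))
  attr(model, "clusters") <- rep(seq_len(k), each = m)
  model
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Load a term-weight table
#'
#' Weights multiply each token's vector before averaging, letting common
#' words be down-weighted by (inverse) frequency. With no file every token
#' gets weight 1 and weighting is a no-op — the documented default.
#'
#' @param path Optional path to a comma-separated `token,weight` file
#'   (UTF-8, no header).
#' @param default_weight Positive weight used for tokens absent from the
#'   table.
#' @return A `weight_table`: named numeric vector of weights with a
#'   `default_weight` attribute.
#' @export
load_term_weights <- function(path = NULL, default_weight = 1) {
  if (!is.finite(default_weight) || default_weight <= 0) {
    stop("default_weight must be finite and > 0")
  }
  if (is.null(path)) {
    return(structure(stats::setNames(numeric(0L), character(0L)),
                     default_weight = default_weight,
                     class = "weight_table"))
  }
  if (!file.exists(path)) stop("weight file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  tokens <- character(length(lines))
  weights <- numeric(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], ",", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      stop("weight file parse error on row ", i, ": expected token,weight")
    }
    w <- suppressWarnings(as.numeric(parts[[2L]]))
    if (is.na(w) || !is.finite(w)) {
      stop("weight file parse error on row ", i, ": non-numeric weight")
    }
    if (w < 0) stop("weight file parse error on row ", i, ": negative weight")
    tokens[[i]] <- trimws(parts[[1L]])
    weights[[i]] <- w
  }
  structure(stats::setNames(weights, tokens),
            default_weight = default_weight,
            class = "weight_table")
}

#' Write a weight table as `token,weight` rows
#' @param table A `weight_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_term_weights <- function(table, path) {
  writeLines(paste(names(table),
                   format(unclass(table), digits = 17, scientific = FALSE,
                          trim = TRUE),
                   sep = ","),
             path, useBytes = TRUE)
  invisible(path)
}

#' Look up a token's weight (falling back to the table default)
#' @param table A `weight_table`.
#' @param token Character scalar.
#' @return Non-negative numeric weight.
#' @export
weight_lookup <- function(table, token) {
  if (token %in% names(table)) unname(table[[token]])
  else attr(table, "default_weight")
}
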
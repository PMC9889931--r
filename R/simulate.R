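#' Configuration for the ideation-sequence simulator
#'
#' Emulates the structure of verbal DT data: each participant produces an
#' ordered sequence of responses per prompt, drawn from planted semantic
#' categories, where each next response stays in the current category with
#' probability `1 - switch_probability` and otherwise jumps to a uniformly
#' chosen other category. Higher switch probability plants higher
#' flexibility.
#'
#' @param embedding Either a [toy_embedding_config()] or an
#'   `embedding_model` produced by [make_toy_embeddings()].
#' @param n_participants Number of simulated participants (>= 1).
#' @param items Character vector of prompt tokens; each must be in the
#'   toy vocabulary. Defaults to the first token of each planted cluster.
#' @param fluency_min,fluency_max Per participant x item, the response
#'   count is drawn uniformly from `fluency_min:fluency_max`.
#' @param switch_probability Chance in \[0, 1\] that each next response
#'   jumps clusters.
#' @param tokens_per_response 1 (default: cluster membership exactly
#'   known) or 2 (exercises multiword averaging; both tokens drawn from
#'   the same cluster).
#' @param seed Integer seed; identical configs give identical output. All
#'   randomness flows from this seed via a named sub-stream per component
#'   (fluency draws, cluster walk, token choice), so adding a stream does
#'   not shift the others.
#' @return An `ideation_sim_config`.
#' @export
ideation_sim_config <- function(embedding = toy_embedding_config(
                                  n_clusters = 5L, tokens_per_cluster = 20L,
                                  dimension = 50L,
                                  within_cluster_spread = 0.1, seed = 101L),
                                n_participants = 100L,
                                items = NULL,
                                fluency_min = 3L, fluency_max = 12L,
                                switch_probability = 0.5,
                                tokens_per_response = 1L,
                                seed = 1L) {
  if (n_participants < 1L) stop("n_participants must be >= 1")
  if (fluency_min < 1L || fluency_max < fluency_min) {
    stop("need 1 <= fluency_min <= fluency_max")
  }
  if (!is.finite(switch_probability) ||
      switch_probability < 0 || switch_probability > 1) {
    stop("switch_probability must lie in [0, 1]")
  }
  if (!tokens_per_response %in% c(1L, 2L)) {
    stop("tokens_per_response must be 1 or 2")
  }
  structure(list(embedding = embedding,
                 n_participants = as.integer(n_participants),
                 items = items,
                 fluency_min = as.integer(fluency_min),
                 fluency_max = as.integer(fluency_max),
                 switch_probability = switch_probability,
                 tokens_per_response = as.integer(tokens_per_response),
                 seed = as.integer(seed)),
            class = "ideation_sim_config")
}

# Derive a named sub-stream seed from the master seed; kept below 2^31.
substream_seed <- function(seed, stream) {
  offset <- c(fluency = 11L, walk = 29L, token = 47L)[[stream]]
  (seed * 1009L + offset * 9973L) %% 2147483629L
}

#' Simulate ordered DT response sequences over a planted-cluster space
#'
#' For each participant x item a fluency count is drawn uniformly in
#' `[fluency_min, fluency_max]`; the first response comes from a random
#' cluster; each subsequent response stays in-cluster with probability
#' `1 - switch_probability`, else moves to a uniformly chosen *other*
#' cluster; `order_index` records generation order. Responses are tokens
#' of the toy vocabulary (one per response by default), so planted
#' cluster membership — hence expected flexibility — is exactly known.
#'
#' @param config An [ideation_sim_config()].
#' @return List with `responses` (a response table as read by
#'   [read_responses()], with an extra `cluster` column recording each
#'   response's planted category), `model` (the `embedding_model` used),
#'   and `items`.
#' @export
simulate_responses <- function(config) {
  stopifnot(inherits(config, "ideation_sim_config"))
  model <- if (inherits(config$embedding, "embedding_model")) {
    config$embedding
  } else {
    make_toy_embeddings(config$embedding)
  }
  clusters <- attr(model, "clusters")
  if (is.null(clusters)) {
    stop("simulate_responses needs a planted-cluster toy embedding model")
  }
  k <- max(clusters)
  vocab <- rownames(model)
  by_cluster <- split(vocab, clusters)

  items <- config$items
  if (is.null(items)) {
    items <- vapply(by_cluster, `[[`, character(1L), 1L)
  }
  if (!all(items %in% vocab)) {
    stop("items outside the toy vocabulary: ",
         paste(setdiff(items, vocab), collapse = ", "))
  }

  n_cells <- config$n_participants * length(items)
  fluencies <- with_seed(substream_seed(config$seed, "fluency"), {
    sample(seq.int(config$fluency_min, config$fluency_max),
           n_cells, replace = TRUE)
  })
  total <- sum(fluencies)
  walks <- with_seed(substream_seed(config$seed, "walk"), {
    list(start = sample.int(k, n_cells, replace = TRUE),
         move = stats::runif(total),
         jump = sample.int(max(k - 1L, 1L), total, replace = TRUE))
  })
  token_pick <- with_seed(substream_seed(config$seed, "token"), {
    stats::runif(total * config$tokens_per_response)
  })

  rows <- vector("list", n_cells)
  pos <- 0L
  cell <- 0L
  for (pi in seq_len(config$n_participants)) {
    pid <- sprintf("p%03d", pi)
    for (it in items) {
      cell <- cell + 1L
      flu <- fluencies[[cell]]
      cl <- integer(flu)
      cl[[1L]] <- walks$start[[cell]]
      for (r in seq_len(flu)) {
        pos <- pos + 1L
        if (r > 1L) {
          if (k > 1L && walks$move[[pos]] < config$switch_probability) {
            others <- setdiff(seq_len(k), cl[[r - 1L]])
            cl[[r]] <- others[[walks$jump[[pos]]]]
          } else {
            cl[[r]] <- cl[[r - 1L]]
          }
        }
      }
      texts <- character(flu)
      for (r in seq_len(flu)) {
        pool <- by_cluster[[cl[[r]]]]
        base_i <- ((pos - flu + r) - 1L) * config$tokens_per_response
        picks <- vapply(seq_len(config$tokens_per_response), function(j) {
          pool[[1L + floor(token_pick[[base_i + j]] * length(pool))]]
        }, character(1L))
        texts[[r]] <- paste(picks, collapse = " ")
      }
      rows[[cell]] <- data.frame(participant_id = pid, item_id = it,
                                 order_index = seq_len(flu),
                                 response = texts, cluster = cl,
                                 stringsAsFactors = FALSE)
    }
  }
  responses <- do.call(rbind, rows)
  rownames(responses) <- NULL
  list(responses = responses, model = model, items = items)
}

#' Configuration for the factor-model data simulator
#'
#' @param loadings Named numeric vector (one-factor) or a variables x
#'   factors matrix with rownames/colnames; zero entries mean no loading.
#' @param factor_cor Factor correlation matrix (default identity).
#' @param residual_pairs Optional list of `list(c("v1","v2"), cov)` pairs
#'   or a named numeric vector `"v1~~v2" = cov` of residual covariances.
#' @param residual_variances Optional per-variable residual variances;
#'   default `1 - communality` (standardized indicators).
#' @param n Sample size.
#' @param seed Integer seed.
#' @return A `factor_sim_config`.
#' @export
factor_sim_config <- function(loadings, factor_cor = NULL,
                              residual_pairs = NULL,
                              residual_variances = NULL,
                              n = 1000L, seed = 1L) {
  if (is.vector(loadings)) {
    loadings <- matrix(loadings, ncol = 1L,
                       dimnames = list(
                         if (!is.null(names(loadings))) names(loadings)
                         else sprintf("v%d", seq_along(loadings)),
                         "F1"))
  }
  if (is.null(rownames(loadings))) {
    rownames(loadings) <- sprintf("v%d", seq_len(nrow(loadings)))
  }
  q <- ncol(loadings)
  if (is.null(factor_cor)) factor_cor <- diag(q)
  stopifnot(nrow(factor_cor) == q, ncol(factor_cor) == q)
  comm <- diag(loadings %*% factor_cor %*% t(loadings))
  if (is.null(residual_variances)) residual_variances <- 1 - comm
  if (any(residual_variances <= 0)) {
    stop("implied residual variances must be positive; lower the loadings ",
         "or supply residual_variances")
  }
  structure(list(loadings = loadings, factor_cor = factor_cor,
                 residual_pairs = residual_pairs,
                 residual_variances = residual_variances,
                 n = as.integer(n), seed = as.integer(seed)),
            class = "factor_sim_config")
}

#' Implied covariance matrix of a factor-model config
#'
#' `Sigma = Lambda Phi Lambda' + Theta`.
#'
#' @param config A [factor_sim_config()].
#' @return Symmetric positive-definite covariance matrix.
#' @export
implied_covariance <- function(config) {
  stopifnot(inherits(config, "factor_sim_config"))
  L <- config$loadings
  Sigma <- L %*% config$factor_cor %*% t(L)
  diag(Sigma) <- diag(Sigma) + config$residual_variances
  if (!is.null(config$residual_pairs)) {
    prs <- config$residual_pairs
    if (is.numeric(prs) && !is.null(names(prs))) {
      prs <- lapply(seq_along(prs), function(i) {
        list(strsplit(names(prs)[[i]], "~~", fixed = TRUE)[[1L]],
             unname(prs[[i]]))
      })
    }
    for (pr in prs) {
      i <- match(pr[[1L]][[1L]], rownames(L))
      j <- match(pr[[1L]][[2L]], rownames(L))
      if (is.na(i) || is.na(j)) stop("residual pair names unknown variable")
      Sigma[i, j] <- Sigma[i, j] + pr[[2L]]
      Sigma[j, i] <- Sigma[i, j]
    }
  }
  dimnames(Sigma) <- list(rownames(L), rownames(L))
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("implied covariance matrix is not positive definite")
  }
  Sigma
}

#' Simulate indicator data from a factor model
#'
#' Multivariate-normal draws with covariance
#' `Lambda Phi Lambda' + Theta`; deterministic given the config's seed.
#'
#' @param config A [factor_sim_config()].
#' @return Numeric data frame, `n` rows, one column per variable.
#' @export
simulate_factor_data <- function(config) {
  Sigma <- implied_covariance(config)
  m <- with_seed(config$seed, {
    MASS::mvrnorm(config$n, mu = rep(0, ncol(Sigma)), Sigma = Sigma)
  })
  colnames(m) <- colnames(Sigma)
  as.data.frame(m)
}
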
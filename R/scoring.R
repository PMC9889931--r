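#' Semantic distance between two response vectors
#'
#' Distance is `1 - cos(u, v)`, the standard semantic-distance scale in
#' embedding-based creativity scoring: 0 for identical directions, 1 for
#' orthogonal vectors, up to 2 for opposite directions. The cosine is
#' clipped to \[-1, 1\] against floating-point overshoot, so the distance
#' always lies in \[0, 2\]. If either vector is undefined the distance is
#' `NA` (undefined propagates; it is never zero-filled).
#'
#' @param u,v `response_vector` objects or raw numeric vectors.
#' @return Numeric scalar in \[0, 2\], or `NA_real_`.
#' @seealso [angle_degrees()]
#' @export
semantic_distance <- function(u, v) {
  cu <- cosine_of(u, v)
  if (is.na(cu)) return(NA_real_)
  1 - cu
}

#' Angle between two response vectors, in degrees
#'
#' The same comparison as [semantic_distance()] reported as
#' `acos(cos(u, v))` in degrees: 0 for identical directions, 90 for
#' orthogonal, 180 for opposite.
#'
#' @inheritParams semantic_distance
#' @return Numeric scalar in \[0, 180\], or `NA_real_`.
#' @export
angle_degrees <- function(u, v) {
  cu <- cosine_of(u, v)
  if (is.na(cu)) return(NA_real_)
  acos(cu) * 180 / pi
}

cosine_of <- function(u, v) {
  a <- as_vec(u)
  b <- as_vec(v)
  if (is.null(a) || is.null(b)) return(NA_real_)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  max(-1, min(1, sum(a * b) / (na * nb)))
}

#' Build consecutive response pairs for one participant-item sequence
#'
#' Order is preserved as given: responses sorted by `order_index` yield
#' exactly `max(n - 1, 0)` pairs, each linking adjacent order indices
#' (first with second, second with third, ...). Flexibility is scored on
#' these pairs, so the original response order must be kept at ingest.
#'
#' @param order_index Integer vector of response positions (>= 1) for one
#'   participant x item; need not be pre-sorted.
#' @param participant_id,item_id Identifiers used only in error messages.
#' @return Data frame with columns `first_order_index`,
#'   `second_order_index`, one row per adjacent pair, in sequence order.
#' @export
consecutive_pairs <- function(order_index, participant_id = NA,
                              item_id = NA) {
  if (anyDuplicated(order_index)) {
    stop("duplicate order_index for participant ", participant_id,
         ", item ", item_id)
  }
  ord <- sort(order_index)
  n <- length(ord)
  if (n < 2L) {
    return(data.frame(first_order_index = integer(0L),
                      second_order_index = integer(0L)))
  }
  data.frame(first_order_index = ord[-n], second_order_index = ord[-1L])
}

#' Score one participant-item response sequence
#'
#' Computes the three DT dimensions for a single prompt:
#' \describe{
#'   \item{fluency}{the count of ingested responses, including responses
#'     whose vector is undefined (all tokens stoplisted or out of
#'     vocabulary).}
#'   \item{flexibility}{semantic distance between consecutive responses:
#'     `flex_sum` sums the defined pair distances, `flex_max` is the
#'     largest, and `flex_mean = flex_sum / fluency` — division by the
#'     response count, not the pair count, is the fluency-confound
#'     correction (see `mean_divisor` to divide by pairs instead).}
#'   \item{originality}{semantic distance between the prompt and each
#'     response, aggregated the same three ways.}
#' }
#' Pairs or prompt-response comparisons touching an undefined vector are
#' skipped, never zero-filled; if no pair (or no response vector) is
#' defined the corresponding aggregate is `NA`.
#'
#' @param responses Data frame with columns `order_index` and `response`
#'   for one participant x item.
#' @param model An `embedding_model`.
#' @param prompt_text The item's prompt (e.g., `"bottle"`); `NULL` skips
#'   originality.
#' @param weights A `weight_table`.
#' @param stoplist Character vector of stoplisted tokens.
#' @param mean_divisor `"fluency"` (default; the confound-corrected mean)
#'   or `"pairs"` (divide `flex_sum` by the number of scored pairs and
#'   `orig_sum` by the number of scored responses).
#' @param metric `"cosine-distance"` (default; `1 - cos`, the primary
#'   score scale) or `"angle-degrees"` (the same comparison reported as
#'   an angle, useful for worked examples).
#' @param participant_id,item_id Identifiers echoed into the result.
#' @return One-row data frame with `participant_id`, `item_id`, `fluency`,
#'   `n_pairs_scored`, `flex_sum`, `flex_mean`, `flex_max`, `orig_sum`,
#'   `orig_mean`, `orig_max`.
#' @export
score_item <- function(responses, model, prompt_text = NULL,
                       weights = load_term_weights(),
                       stoplist = default_stoplist(),
                       mean_divisor = c("fluency", "pairs"),
                       metric = c("cosine-distance", "angle-degrees"),
                       participant_id = NA, item_id = NA) {
  mean_divisor <- match.arg(mean_divisor)
  metric <- match.arg(metric)
  pair_score <- if (metric == "cosine-distance") semantic_distance
                else angle_degrees
  stopifnot(is.data.frame(responses),
            all(c("order_index", "response") %in% names(responses)))
  if (anyDuplicated(responses$order_index)) {
    stop("duplicate order_index for participant ", participant_id,
         ", item ", item_id)
  }
  responses <- responses[order(responses$order_index), , drop = FALSE]
  n <- nrow(responses)

  vecs <- lapply(responses$response, vectorize_response,
                 model = model, weights = weights, stoplist = stoplist)

  # consecutive-pair flexibility
  pair_d <- numeric(0L)
  if (n >= 2L) {
    pair_d <- vapply(seq_len(n - 1L), function(i) {
      pair_score(vecs[[i]], vecs[[i + 1L]])
    }, numeric(1L))
  }
  defined <- pair_d[!is.na(pair_d)]
  n_pairs <- length(defined)
  flex_sum <- if (n_pairs > 0L) sum(defined) else NA_real_
  flex_max <- if (n_pairs > 0L) max(defined) else NA_real_
  flex_mean <- if (n_pairs > 0L) {
    flex_sum / if (mean_divisor == "fluency") n else n_pairs
  } else NA_real_

  # prompt-to-response originality
  orig_sum <- orig_mean <- orig_max <- NA_real_
  if (!is.null(prompt_text)) {
    pvec <- vectorize_response(prompt_text, model,
                               weights = weights, stoplist = stoplist)
    if (!is.null(pvec$vector) && n > 0L) {
      od <- vapply(vecs, function(v) pair_score(pvec, v), numeric(1L))
      od_def <- od[!is.na(od)]
      if (length(od_def) > 0L) {
        orig_sum <- sum(od_def)
        orig_max <- max(od_def)
        orig_mean <- orig_sum /
          if (mean_divisor == "fluency") n else length(od_def)
      }
    }
  }

  data.frame(participant_id = participant_id, item_id = item_id,
             fluency = n, n_pairs_scored = n_pairs,
             flex_sum = flex_sum, flex_mean = flex_mean,
             flex_max = flex_max,
             orig_sum = orig_sum, orig_mean = orig_mean,
             orig_max = orig_max,
             stringsAsFactors = FALSE)
}

#' Score a full response table
#'
#' Applies [score_item()] to every participant x item group of a response
#' table. Scoring is a pure per-group computation: row order in the input
#' does not affect any score. Prompts default to the item identifier
#' itself (the convention for object-prompt tasks where the item *is* the
#' prompt word); a named `prompts` vector overrides this.
#'
#' @param responses Data frame with columns `participant_id`, `item_id`,
#'   `order_index`, `response` (see [read_responses()]). Rows whose
#'   response is empty after whitespace stripping are dropped with a
#'   warning.
#' @param model An `embedding_model`.
#' @param prompts Optional named character vector mapping `item_id` to
#'   prompt text; unnamed items fall back to their `item_id`.
#' @inheritParams score_item
#' @return Data frame of per-item scores, one row per participant x item,
#'   ordered by participant then item.
#' @export
score_responses <- function(responses, model, prompts = NULL,
                            weights = load_term_weights(),
                            stoplist = default_stoplist(),
                            mean_divisor = c("fluency", "pairs"),
                            metric = c("cosine-distance", "angle-degrees")) {
  mean_divisor <- match.arg(mean_divisor)
  metric <- match.arg(metric)
  stopifnot(is.data.frame(responses),
            all(c("participant_id", "item_id", "order_index", "response")
                %in% names(responses)))
  blank <- !nzchar(trimws(as.character(responses$response)))
  if (any(blank)) {
    warning("dropping ", sum(blank), " empty response row(s)")
    responses <- responses[!blank, , drop = FALSE]
  }
  groups <- split(responses,
                  list(responses$participant_id, responses$item_id),
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    item <- as.character(g$item_id[[1L]])
    prompt <- if (!is.null(prompts) && item %in% names(prompts)) {
      prompts[[item]]
    } else item
    score_item(g, model, prompt_text = prompt, weights = weights,
               stoplist = stoplist, mean_divisor = mean_divisor,
               metric = metric,
               participant_id = g$participant_id[[1L]], item_id = item)
  })
  out <- do.call(rbind, unname(out))
  out <- out[order(out$participant_id, out$item_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate per-item scores into per-participant battery summaries
#'
#' For each participant, averages and maximizes across the battery's
#' items: fluency mean is the sum of item fluencies divided by the number
#' of items, fluency max the highest item fluency; the flexibility and
#' originality aggregates are averaged/maximized over items with defined
#' scores (undefined cells stay missing, never zero — a zero means
#' identical adjacent ideas, not absence).
#'
#' @param item_scores Data frame from [score_responses()].
#' @return Data frame with one row per participant: `n_items`,
#'   `fluency_mean_across_items`, `fluency_max_across_items`, and
#'   across-item means/maxima of `flex_mean`, `flex_max`, `orig_mean`,
#'   `orig_max`.
#' @export
aggregate_battery <- function(item_scores) {
  stopifnot(is.data.frame(item_scores),
            all(c("participant_id", "item_id", "fluency") %in%
                names(item_scores)))
  groups <- split(item_scores, item_scores$participant_id, drop = TRUE)
  agg1 <- function(x, f) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) NA_real_ else f(x)
  }
  out <- lapply(groups, function(g) {
    if (anyDuplicated(g$item_id)) {
      stop("duplicate item for participant ", g$participant_id[[1L]])
    }
    data.frame(
      participant_id = g$participant_id[[1L]],
      n_items = nrow(g),
      fluency_mean_across_items = sum(g$fluency) / nrow(g),
      fluency_max_across_items = max(g$fluency),
      flex_mean_across_items = agg1(g$flex_mean, mean),
      flex_max_across_items = agg1(g$flex_max, max),
      orig_mean_across_items = agg1(g$orig_mean, mean),
      orig_max_across_items = agg1(g$orig_max, max),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, unname(out))
  out <- out[order(out$participant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a response table
#'
#' Comma-separated, UTF-8, header
#' `participant_id,item_id,order_index,response`; rows need not be
#' pre-sorted. Empty-response rows are dropped with a warning;
#' `order_index` must be unique within each participant x item.
#'
#' @param path Path to the CSV file.
#' @return Data frame with the four columns, `order_index` integer.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop("response file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character",
                                       "integer", "character"),
                        fileEncoding = "UTF-8")
  need <- c("participant_id", "item_id", "order_index", "response")
  if (!all(need %in% names(df))) {
    stop("response file must have header: ", paste(need, collapse = ","))
  }
  blank <- !nzchar(trimws(df$response))
  if (any(blank)) {
    warning("dropping ", sum(blank), " empty response row(s) at ingest")
    df <- df[!blank, , drop = FALSE]
  }
  key <- paste(df$participant_id, df$item_id, df$order_index, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate order_index ", bad$order_index, " for participant ",
         bad$participant_id, ", item ", bad$item_id)
  }
  rownames(df) <- NULL
  df[need]
}

#' Write a response table
#' @param responses Data frame as read by [read_responses()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Write a score table (per-item or battery)
#'
#' Numeric cells are printed with 6 significant digits; undefined scores
#' become empty cells, never 0.
#'
#' @param scores Data frame from [score_responses()] or
#'   [aggregate_battery()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  fmt <- scores
  for (nm in names(fmt)) {
    if (is.double(fmt[[nm]])) {
      v <- fmt[[nm]]
      s <- ifelse(is.na(v), "", format(signif(v, 6L), trim = TRUE,
                                       scientific = FALSE))
      fmt[[nm]] <- s
    }
  }
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}
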
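# Bundled English function-word stoplist (~100 words). Overridable via
# load_stoplist(); removal happens before embedding lookup.
.default_stoplist <- c(
  "a", "an", "the", "and", "or", "but", "nor", "so", "yet", "for",
  "of", "in", "on", "at", "to", "from", "by", "with", "about", "as",
  "into", "onto", "over", "under", "up", "down", "out", "off", "than",
  "i", "me", "my", "mine", "we", "us", "our", "ours", "you", "your",
  "yours", "he", "him", "his", "she", "her", "hers", "it", "its",
  "they", "them", "their", "theirs", "this", "that", "these", "those",
  "is", "am", "are", "was", "were", "be", "been", "being", "do",
  "does", "did", "have", "has", "had", "will", "would", "shall",
  "should", "can", "could", "may", "might", "must", "not", "no",
  "if", "then", "else", "when", "while", "where", "which", "who",
  "whom", "whose", "what", "how", "why", "there", "here", "all",
  "any", "both", "each", "few", "more", "most", "some", "such",
  "only", "own", "same", "too", "very", "just", "also"
)

#' The bundled default stoplist
#'
#' A small English function-word list removed from responses before
#' embedding lookup. Stoplisting common words keeps multiword response
#' vectors from being dragged toward high-frequency function words.
#'
#' @return Character vector of lower-case tokens.
#' @export
default_stoplist <- function() .default_stoplist

#' Load a stoplist file
#'
#' One token per line, UTF-8; `#` starts a comment; blank lines ignored.
#'
#' @param path Path to the stoplist file, or `NULL` for the bundled default.
#' @return Character vector of lower-case tokens.
#' @export
load_stoplist <- function(path = NULL) {
  if (is.null(path)) return(default_stoplist())
  if (!file.exists(path)) stop("stoplist file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  tolower(lines[nzchar(lines)])
}

#' Tokenize free text
#'
#' Lower-cases and splits on runs of non-word characters; hyphens and
#' apostrophes act as separators; digit strings are kept as tokens;
#' underscore counts as a word character (the usual `\\w` convention,
#' which also keeps compound vocabulary entries like `c1_t4` intact).
#' Total function: any input (including `""`) yields a (possibly empty)
#' character vector.
#'
#' @param text Character scalar.
#' @return Ordered character vector of tokens.
#' @examples
#' tokenize("Musical instrument")  # "musical" "instrument"
#' tokenize("bird-house!")         # "bird" "house"
#' @export
tokenize <- function(text) {
  if (length(text) != 1L || is.na(text)) return(character(0L))
  parts <- strsplit(tolower(text), "[^a-z0-9_]+")[[1L]]
  parts[nzchar(parts)]
}

#' Represent one free-text response as a weighted-average vector
#'
#' Tokens are stoplisted, then looked up in the embedding model; the
#' response vector is the weighted arithmetic mean
#' \eqn{\sum_t w(t)\,v(t) / \sum_t w(t)} over surviving in-vocabulary
#' tokens. Out-of-vocabulary tokens are dropped (and counted), never
#' imputed. When no token survives — or the surviving weights sum to zero —
#' the vector is *undefined* (`NULL`), never a zero vector: a fabricated
#' zero would fake maximal/minimal distances downstream.
#'
#' @param text Character scalar, the free-text response.
#' @param model An `embedding_model`.
#' @param weights A `weight_table` (default: uniform weight 1).
#' @param stoplist Character vector of tokens to remove (default: bundled
#'   English list; use `character(0)` to disable).
#' @return A `response_vector`: list with `vector` (numeric or `NULL`),
#'   `tokens_used`, `tokens_dropped_stoplist`, `tokens_dropped_oov`.
#' @export
vectorize_response <- function(text, model,
                               weights = load_term_weights(),
                               stoplist = default_stoplist()) {
  stopifnot(inherits(model, "embedding_model"))
  toks <- tokenize(text)
  keep <- !(toks %in% stoplist)
  n_stop <- sum(!keep)
  toks <- toks[keep]

  d <- ncol(model)
  acc <- numeric(d)
  wsum <- 0
  used <- 0L
  oov <- 0L
  for (tok in toks) {
    v <- embedding_lookup(model, tok)
    if (is.null(v)) {
      oov <- oov + 1L
      next
    }
    w <- weight_lookup(weights, tok)
    acc <- acc + w * v
    wsum <- wsum + w
    used <- used + 1L
  }

  vec <- NULL
  if (used >= 1L) {
    if (wsum > 0) {
      vec <- acc / wsum
    } else {
      warning("surviving token weights sum to zero; response vector undefined")
      used <- 0L
    }
  }
  structure(list(vector = vec,
                 tokens_used = used,
                 tokens_dropped_stoplist = n_stop,
                 tokens_dropped_oov = oov),
            class = "response_vector")
}

#' @export
print.response_vector <- function(x, ...) {
  state <- if (is.null(x$vector)) "undefined" else
    paste0("dim ", length(x$vector))
  cat("<response_vector> ", state,
      " (used ", x$tokens_used,
      ", stoplisted ", x$tokens_dropped_stoplist,
      ", oov ", x$tokens_dropped_oov, ")\n", sep = "")
  invisible(x)
}

# Extract the raw numeric vector from a response_vector or pass numerics
# through; NULL marks the undefined state.
as_vec <- function(x) {
  if (inherits(x, "response_vector")) x$vector
  else if (is.numeric(x)) x
  else NULL
}
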
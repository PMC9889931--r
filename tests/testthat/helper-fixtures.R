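# Build an embedding model from a named list of numeric vectors by writing
# a GloVe-format file and loading it back, so fixtures also exercise the
# loader path.
model_from_vectors <- function(vectors) {
  path <- tempfile(fileext = ".txt")
  lines <- vapply(names(vectors), function(tok) {
    paste(tok, paste(format(vectors[[tok]], digits = 17, trim = TRUE,
                            scientific = FALSE), collapse = " "))
  }, character(1L))
  writeLines(lines, path)
  load_embeddings(path)
}

# Three unit vectors whose consecutive cosines are 0.8 and 0.6, giving the
# worked pair distances 0.2 and 0.4.
worked_vectors <- list(alpha = c(1, 0), beta = c(0.8, 0.6), gamma = c(0, 1))

worked_responses <- data.frame(
  participant_id = "p1", item_id = "alpha",
  order_index = 1:3, response = c("alpha", "beta", "gamma"),
  stringsAsFactors = FALSE)

# All pairwise cosine similarities of an embedding matrix, split into
# within-cluster and between-cluster sets (brute force).
pairwise_cosine_split <- function(model) {
  cl <- attr(model, "clusters")
  m <- unclass(model)
  m <- m / sqrt(rowSums(m^2))
  cs <- tcrossprod(m)
  idx <- which(upper.tri(cs), arr.ind = TRUE)
  same <- cl[idx[, 1L]] == cl[idx[, 2L]]
  list(within = cs[upper.tri(cs)][same], between = cs[upper.tri(cs)][!same])
}
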
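# Face-analysis geometry: cosine-rule alignment angle, prototype
# classification over caller-supplied embeddings, rolling majority vote.

#' Facial alignment angle by the cosine rule
#'
#' Given the triangle with `a` the eye-to-eye distance and `b`, `c` the
#' distances from each eye to a reference landmark (nose tip or a midpoint
#' below the eyes), returns the angle at the reference vertex:
#' `A = arccos((b^2 + c^2 - a^2) / (2 b c))` in degrees, in `[0, 180]`.
#'
#' @param a,b,c triangle side lengths (same units); `b, c > 0`, triangle
#'   inequality must hold (`a = 0` is allowed and yields 0 degrees).
#' @return angle in degrees.
#' @export
alignment_angle <- function(a, b, c) {
  for (v in list(a = a, b = b, c = c))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      abort_geometry("side lengths must be single finite nonnegative numbers")
  if (b == 0 || c == 0)
    abort_geometry("sides b and c must be positive")
  if (a > b + c || b > a + c || c > a + b)
    abort_geometry("triangle inequality violated")
  cosA <- (b^2 + c^2 - a^2) / (2 * b * c)
  cosA <- min(max(cosA, -1), 1)   # guard float round-off at the boundaries
  acos(cosA) * 180 / pi
}

#' Alignment angle from face landmarks
#'
#' Convenience wrapper computing the triangle sides from a
#' [face_observation()]'s `left_eye`, `right_eye` and `reference_point`
#' landmarks.
#'
#' @param obs a [face_observation()] with the three landmarks.
#' @return angle in degrees, as [alignment_angle()].
#' @export
alignment_angle_landmarks <- function(obs) {
  lm <- obs$landmarks
  need <- c("left_eye", "right_eye", "reference_point")
  if (is.null(lm) || !all(need %in% names(lm)))
    abort_geometry("landmarks left_eye, right_eye, reference_point required")
  d <- function(p, q) sqrt(sum((unlist(p) - unlist(q))^2))
  alignment_angle(a = d(lm$left_eye, lm$right_eye),
                  b = d(lm$left_eye, lm$reference_point),
                  c = d(lm$right_eye, lm$reference_point))
}

#' Labeled prototype set
#'
#' @param vectors numeric matrix, one prototype per row, or a list of
#'   equal-length numeric vectors.
#' @param labels class label per prototype.
#' @return object of class `prototype_set`.
#' @export
prototype_set <- function(vectors, labels) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 1L) abort_config("need at least one prototype")
  if (length(labels) != nrow(vectors))
    abort_config("one label per prototype required")
  structure(list(vectors = vectors, labels = as.character(labels),
                 d = ncol(vectors)),
            class = "prototype_set")
}

check_embedding <- function(v, protos) {
  if (!inherits(protos, "prototype_set"))
    abort_config("`protos` must be a prototype_set")
  if (length(v) != protos$d)
    abort_classification(sprintf("embedding dimension %d != prototype dimension %d",
                                 length(v), protos$d))
  as.numeric(v)
}

#' Classify an embedding by cosine similarity to prototypes
#'
#' Returns the label of the prototype maximising
#' `v . v_j / (||v|| ||v_j||)`. Ties are broken by the first prototype in
#' declared order. Invariant to positive rescaling of `v`.
#'
#' @param v numeric embedding, nonzero norm.
#' @param protos a [prototype_set()] with no zero-norm prototype.
#' @return list with `label` and `similarity`.
#' @export
classify_cosine <- function(v, protos) {
  v <- check_embedding(v, protos)
  nv <- sqrt(sum(v^2))
  if (nv == 0) abort_classification("zero-norm embedding")
  np <- sqrt(rowSums(protos$vectors^2))
  if (any(np == 0)) abort_classification("zero-norm prototype in cosine mode")
  sims <- as.numeric(protos$vectors %*% v) / (np * nv)
  j <- which.max(sims)   # which.max returns the first maximum: the tie rule
  list(label = protos$labels[j], similarity = sims[j])
}

#' Classify an embedding by Euclidean distance to prototypes
#'
#' Returns the label of the nearest prototype (`argmin` of
#' `sqrt(sum((v - v_j)^2))`); ties broken by the first prototype in declared
#' order. Invariant to a common translation of `v` and all prototypes.
#'
#' @param v numeric embedding.
#' @param protos a [prototype_set()].
#' @return list with `label` and `distance`.
#' @export
classify_euclidean <- function(v, protos) {
  v <- check_embedding(v, protos)
  d2 <- rowSums(sweep(protos$vectors, 2, v)^2)
  j <- which.min(d2)
  list(label = protos$labels[j], distance = sqrt(d2[j]))
}

#' Rolling majority vote
#'
#' Most frequent label over the last `n_required` entries of a label stream
#' (the age pipeline collects 30 rolling classifier outputs and reports the
#' mode). With fewer than `n_required` labels the vote is `pending`. Ties are
#' broken in favour of the tied label seen most recently.
#'
#' @param labels character vector of labels in arrival order.
#' @param n_required number of samples the vote is taken over (default 30).
#' @return list with `status` (`"ok"` or `"pending"`), `label`, `count`, and
#'   `confidence_fraction = count / n_required`.
#' @export
majority_vote <- function(labels, n_required = 30L) {
  labels <- as.character(labels)
  if (length(labels) < n_required)
    return(list(status = "pending", label = NA_character_,
                count = NA_integer_, confidence_fraction = NA_real_))
  last <- labels[(length(labels) - n_required + 1L):length(labels)]
  counts <- table(last)
  top <- max(counts)
  tied <- names(counts)[counts == top]
  label <- if (length(tied) == 1L) tied else {
    # most recent occurrence among tied labels wins
    tied[which.max(vapply(tied, function(l) max(which(last == l)), 0L))]
  }
  list(status = "ok", label = label, count = as.integer(top),
       confidence_fraction = as.integer(top) / n_required)
}

#' Deterministic toy embedder
#'
#' Stand-in for a CNN feature extractor, for tests and examples: hashes a
#' label string into a reproducible unit vector of dimension `d`. Any
#' function returning fixed-dimension numeric vectors can take its place in
#' the classification contract.
#'
#' @param label character scalar.
#' @param d embedding dimension.
#' @return numeric unit vector of length `d`.
#' @export
toy_embedder <- function(label, d = 8L) {
  codes <- utf8ToInt(as.character(label))
  seed <- sum(codes * seq_along(codes)) %% 100000L
  v <- with_seed(seed, stats::rnorm(d))
  v / sqrt(sum(v^2))
}
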
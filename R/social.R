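.parse_neighbours <- function(x) {
  if (is.na(x) || x == "") character(0) else strsplit(x, ";", fixed = TRUE)[[1L]]
}

#' Build a dyadic association (friendship) matrix from proximity scans
#'
#' The friendship score of a dyad is the frequency with which the two
#' individuals were recorded as close neighbours during proximity scans:
#' entry `(i, j)` counts the scans in which one of the pair was the focal
#' and the other appeared in its neighbour set, pooled symmetrically.
#' `mode = "rate"` divides each dyad's count by the combined scan effort of
#' the two individuals, for data where effort is not balanced.
#'
#' @param scans data.frame `focal_id, scan_index, neighbour_ids`
#'   (';'-separated neighbour ids).
#' @param ids optional roster; defaults to all ids seen. Unknown neighbour
#'   ids are an error.
#' @param mode `"count"` (default) or `"rate"`.
#' @return symmetric matrix with zero diagonal, dimnames = ids.
#' @export
build_association_matrix <- function(scans, ids = NULL,
                                     mode = c("count", "rate")) {
  mode <- match.arg(mode)
  if (nrow(scans) == 0L) stop("no scans provided", call. = FALSE)
  nb <- lapply(scans$neighbour_ids, .parse_neighbours)
  seen <- unique(c(scans$focal_id, unlist(nb)))
  if (is.null(ids)) ids <- sort(seen)
  unknown <- setdiff(seen, ids)
  if (length(unknown) > 0L)
    stop(sprintf("unknown ids in scans: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  fi <- match(scans$focal_id, ids)
  for (r in seq_along(nb)) {
    j <- match(nb[[r]], ids)
    if (length(j) > 0L) {
      m[fi[r], j] <- m[fi[r], j] + 1
    }
  }
  m <- m + t(m)
  diag(m) <- 0
  if (mode == "rate") {
    effort <- vapply(ids, function(id) sum(scans$focal_id == id), numeric(1L))
    denom <- outer(effort, effort, "+")
    denom[denom == 0] <- 1
    m <- m / denom
    diag(m) <- 0
  }
  m
}

#' Z-score the off-diagonal dyads of a matrix
#'
#' Standardises dyadic values to mean 0, sd 1 (the diagonal is untouched).
#' For a symmetric matrix the statistics are computed over the unique
#' (upper-triangle) dyads.
#'
#' @param m a square matrix, or a plain numeric vector of dyadic values
#'   (standardised directly).
#' @param sd_type `"sample"` (n-1 denominator, default, matching [scale()])
#'   or `"population"` (n denominator).
#' @return the matrix with standardised off-diagonal entries (or the
#'   standardised vector).
#' @export
zscore_dyadic <- function(m, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (is.numeric(m) && is.null(dim(m))) {
    if (length(unique(m)) < 2L)
      stop("dyadic values have zero variance; cannot standardise",
           call. = FALSE)
    s <- if (sd_type == "sample") stats::sd(m) else
      sqrt(mean((m - mean(m)) ^ 2))
    return((m - mean(m)) / s)
  }
  m <- as.matrix(m)
  sym <- isSymmetric(unname(m))
  vals <- if (sym) m[upper.tri(m)] else m[row(m) != col(m)]
  if (length(unique(vals)) < 2L)
    stop("dyadic values have zero variance; cannot standardise",
         call. = FALSE)
  mu <- mean(vals)
  s <- stats::sd(vals)
  if (sd_type == "population")
    s <- sqrt(mean((vals - mu) ^ 2))
  off <- row(m) != col(m)
  m[off] <- (m[off] - mu) / s
  m
}

#' Sequential Elo ratings from unidirectional agonistic events
#'
#' Processes winner/loser events in order. Before each event the expected
#' probability that the eventual winner wins is the logistic
#' `E = 1 / (1 + 10^((R_loser - R_winner) / 400))`; the winner then gains
#' `k * (1 - E)` and the loser loses the same amount, so with a common `k`
#' the rating sum is conserved at `n * start`.
#'
#' @param conflicts data.frame `winner_id, loser_id, order`.
#' @param ids optional roster (individuals without events keep `start`).
#' @param k update constant.
#' @param start initial rating.
#' @return an object of class `"elo_state"`: `ratings` (named vector), `k`,
#'   `start_value` and `history` (events x individuals rating trajectory).
#' @export
elo_ratings <- function(conflicts, ids = NULL, k = 100, start = 1000) {
  if (is.null(ids))
    ids <- sort(unique(c(conflicts$winner_id, conflicts$loser_id)))
  unknown <- setdiff(unique(c(conflicts$winner_id, conflicts$loser_id)), ids)
  if (length(unknown) > 0L)
    stop(sprintf("unknown ids in conflicts: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (nrow(conflicts) > 0L && any(conflicts$winner_id == conflicts$loser_id))
    stop("winner and loser must differ", call. = FALSE)
  if (!is.null(conflicts$order)) conflicts <- conflicts[order(conflicts$order), ]
  r <- stats::setNames(rep(as.numeric(start), length(ids)), ids)
  hist <- matrix(NA_real_, nrow(conflicts), length(ids),
                 dimnames = list(NULL, ids))
  for (e in seq_len(nrow(conflicts))) {
    w <- conflicts$winner_id[e]; l <- conflicts$loser_id[e]
    expw <- 1 / (1 + 10 ^ ((r[l] - r[w]) / 400))
    delta <- k * (1 - expw)
    r[w] <- r[w] + delta
    r[l] <- r[l] - delta
    hist[e, ] <- r
  }
  structure(list(ratings = r, k = k, start_value = start, history = hist),
            class = "elo_state")
}

#' @export
print.elo_state <- function(x, ...) {
  cat(sprintf("<elo_state: %d individuals, %d events, k = %g, start = %g>\n",
              length(x$ratings), nrow(x$history), x$k, x$start_value))
  print(round(sort(x$ratings, decreasing = TRUE), 1))
  invisible(x)
}

#' Eigenvector centrality of a weighted association network
#'
#' Computes each individual's component of the dominant eigenvector of the
#' association matrix (via `igraph::eigen_centrality` on the weighted
#' undirected graph), max-normalised to 1, and partitions the group into
#' the `ceil(n/2)` most central individuals (the central set) and the rest
#' (peripheral), ties broken by id order.
#'
#' @param m symmetric non-negative association matrix with dimnames.
#' @return an object of class `"centrality_result"`: `scores` (named, in
#'   \[0, 1\]), `central_set`, `peripheral_set`.
#' @export
eigenvector_centrality <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m)))
    rownames(m) <- colnames(m) <- sprintf("I%02d", seq_len(nrow(m)))
  if (all(m == 0)) stop("association matrix is all zero", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  sc <- igraph::eigen_centrality(g)$vector  # max-normalised to 1
  sc <- sc[rownames(m)]
  ord <- order(-sc, names(sc))
  n_central <- ceiling(length(sc) / 2)
  structure(list(scores = sc,
                 central_set = sort(names(sc)[ord[seq_len(n_central)]]),
                 peripheral_set = sort(names(sc)[ord[-seq_len(n_central)]])),
            class = "centrality_result")
}

#' @export
print.centrality_result <- function(x, ...) {
  cat(sprintf("<centrality: %d central / %d peripheral>\n",
              length(x$central_set), length(x$peripheral_set)))
  print(round(sort(x$scores, decreasing = TRUE), 3))
  invisible(x)
}

.upper <- function(m) m[upper.tri(m)]

#' Mantel permutation test of matrix correlation
#'
#' Pearson correlation between the upper-triangle dyads of two symmetric
#' matrices over the same individuals, with a one-tailed (greater)
#' permutation null built by jointly permuting the rows and columns of the
#' second matrix; `p = (#{r_perm >= r_obs} + 1) / (n_perm + 1)`.
#'
#' @param m1,m2 symmetric matrices over the same individuals.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return an object of class `"mantel_result"`: `r`, `p_value`, `n_perm`,
#'   `tail = "greater"`.
#' @export
mantel_test <- function(m1, m2, n_perm = 5000, seed = 1) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!all(dim(m1) == dim(m2)))
    stop("matrices must have identical dimensions", call. = FALSE)
  r_obs <- stats::cor(.upper(m1), .upper(m2))
  set.seed(seed)
  n <- nrow(m1)
  r_perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    r_perm[i] <- stats::cor(.upper(m1), .upper(m2[p, p]))
  }
  structure(list(r = r_obs,
                 p_value = (sum(r_perm >= r_obs) + 1) / (n_perm + 1),
                 n_perm = as.integer(n_perm), tail = "greater"),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (one-tailed, %d permutations): r = %.3f, p = %s\n",
              x$n_perm, x$r, format.pval(x$p_value)))
  invisible(x)
}

#' Split-half stability of the association network
#'
#' Splits the scan records into two adjacent chronological blocks at the
#' given fraction, builds an association matrix from each block, and
#' returns their Mantel comparison. A significant positive correlation
#' indicates a stable (non-random) social structure over time.
#'
#' @param scans a scan table (see [build_association_matrix()]).
#' @param split fraction of records in the first block, in (0, 1).
#' @param ids optional roster.
#' @param n_perm,seed passed to [mantel_test()].
#' @return a `"mantel_result"`.
#' @export
stability_split <- function(scans, split = 0.5, ids = NULL, n_perm = 5000,
                            seed = 1) {
  if (split <= 0 || split >= 1) stop("`split` must be in (0, 1)", call. = FALSE)
  scans <- scans[order(scans$scan_index), ]
  n1 <- floor(split * nrow(scans))
  if (n1 < 1L || n1 >= nrow(scans))
    stop("split leaves an empty block; use more scans or a milder split",
         call. = FALSE)
  if (is.null(ids))
    ids <- sort(unique(c(scans$focal_id,
                         unlist(lapply(scans$neighbour_ids,
                                       .parse_neighbours)))))
  a1 <- build_association_matrix(scans[seq_len(n1), ], ids = ids)
  a2 <- build_association_matrix(scans[-seq_len(n1), ], ids = ids)
  if (all(a1 == 0) || all(a2 == 0))
    stop("a block contains no co-occurrences; use a larger block",
         call. = FALSE)
  mantel_test(a1, a2, n_perm = n_perm, seed = seed)
}

#' Binary maternal-kinship matrix from matriline labels
#'
#' Dyads within the same matriline are coded related (1), all others
#' unrelated (0); the diagonal is 1.
#'
#' @param matrilines named character vector (names = individual ids) or a
#'   data.frame `individual_id, matriline`.
#' @return symmetric 0/1 matrix.
#' @export
kinship_matrix <- function(matrilines) {
  if (is.data.frame(matrilines))
    matrilines <- stats::setNames(matrilines$matriline,
                                  matrilines$individual_id)
  if (is.null(names(matrilines)) || any(is.na(matrilines)) ||
      any(matrilines == ""))
    stop("every individual must carry a matriline label", call. = FALSE)
  k <- outer(matrilines, matrilines, "==") * 1
  dimnames(k) <- list(names(matrilines), names(matrilines))
  k
}

# Candidate females for a subject: not the subject, female sex.
.eligible_females <- function(subject, ids, sexes) {
  setdiff(ids[sexes[ids] == "F"], subject)
}

# Deterministic argmax/argmin over a named score vector, ties by id order.
.pick <- function(scores, decreasing = TRUE) {
  ord <- order(if (decreasing) -scores else scores, names(scores))
  names(scores)[ord[1L]]
}

#' Select the caller dyad for a playback condition
#'
#' Implements the rule set of the six playback conditions. Callers are
#' always female and never the subject. Writing `f(x, y)` for the
#' friendship score of `x` and `y`, and "low with the subject" for a score
#' below the subject's median over eligible females:
#'
#' * Condition 1: Caller A = the female with the highest `f(subject, .)`;
#'   Caller B = among females low with the subject, the one with the
#'   highest `f(A, .)` (a friend of the subject's friend).
#' * Condition 2: A as in 1; B = among females low with the subject, the
#'   one with the lowest `f(A, .)` (a non-friend of both).
#' * Condition 3: A = the female with the lowest `f(subject, .)`; B =
#'   among females low with the subject, the one with the highest
#'   `f(A, .)` (friends with each other, neither a friend of the subject).
#' * Condition 4: A as in 3; B = among females low with the subject, the
#'   one with the lowest `f(A, .)`.
#' * Condition 5: A = the highest-centrality female matriarch whose
#'   matriline holds another eligible female; B = the same-matriline female
#'   with the highest `f(A, .)`.
#' * Condition 6: A as in 5; B = the out-matriline female with the highest
#'   `f(A, .)`.
#'
#' Conditions 3 and 4 are infeasible for central subjects (for a
#' well-connected subject no pair of mutual friends that are both
#' non-friends of the subject exists, so these conditions are run on
#' peripheral individuals only); `NULL` is returned for any condition
#' whose constraints cannot be met. Ties are broken by id order, so the
#' selection is a pure function of its inputs.
#'
#' @param subject subject id.
#' @param assoc association (friendship) matrix.
#' @param kin binary kinship matrix from [kinship_matrix()].
#' @param sexes named `"F"`/`"M"` vector.
#' @param centrality a [eigenvector_centrality()] result.
#' @param condition integer 1..6.
#' @return `c(caller_A, caller_B)` or `NULL` when infeasible.
#' @export
select_condition_dyads <- function(subject, assoc, kin, sexes, centrality,
                                   condition) {
  ids <- rownames(assoc)
  if (!subject %in% ids) stop(sprintf("unknown subject '%s'", subject),
                              call. = FALSE)
  stopifnot(condition %in% 1:6)
  females <- .eligible_females(subject, ids, sexes)
  if (length(females) < 3L) return(NULL)
  fsub <- stats::setNames(assoc[subject, females], females)

  if (condition %in% 1:4) {
    if (condition %in% 3:4 && subject %in% centrality$central_set)
      return(NULL)
    A <- if (condition %in% 1:2) .pick(fsub) else .pick(fsub, decreasing = FALSE)
    low <- names(fsub)[fsub < stats::median(fsub)]
    cand <- setdiff(low, A)
    if (length(cand) == 0L) return(NULL)
    fa <- stats::setNames(assoc[A, cand], cand)
    B <- if (condition %in% c(1, 3)) .pick(fa) else .pick(fa, decreasing = FALSE)
    return(c(A, B))
  }

  # conditions 5-6: matriarch = highest-centrality female of her matriline
  mat_of <- function(id) names(which(kin[id, ] == 1))
  cent <- centrality$scores[females]
  matriarchs <- character(0)
  for (f in females[order(-cent[females], females)]) {
    kinfolk <- setdiff(intersect(mat_of(f), females), f)
    is_matriarch <- all(centrality$scores[f] >=
                          centrality$scores[intersect(mat_of(f), females)])
    if (is_matriarch) matriarchs <- c(matriarchs, f)
  }
  for (A in matriarchs) {
    kinfolk <- setdiff(intersect(mat_of(A), females), A)
    nonkin <- setdiff(females, c(A, mat_of(A)))
    if (condition == 5 && length(kinfolk) > 0L) {
      fa <- stats::setNames(assoc[A, kinfolk], kinfolk)
      return(c(A, .pick(fa)))
    }
    if (condition == 6 && length(nonkin) > 0L) {
      fa <- stats::setNames(assoc[A, nonkin], nonkin)
      return(c(A, .pick(fa)))
    }
  }
  NULL
}
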
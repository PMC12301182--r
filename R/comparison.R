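#' Event keys shared by implicit and explicit methods
#'
#' An event is identified by its (family, recipient branch) pair; donors are
#' ignored so that donor-bearing and donor-less inference sets can be
#' intersected.
#'
#' @param events Gain-event tibble (one stringency level or any subset).
#' @return Character vector of unique keys.
#' @export
event_keys <- function(events) {
  unique(paste(events$family_id, events$recipient_branch, sep = "\r"))
}

#' Overlap Coefficient of two event-key sets
#'
#' |A intersect B| / min(|A|, |B|): 1 when one set contains the other, 0 when
#' disjoint.
#'
#' @param a,b Non-empty character vectors of event keys.
#' @return A number in [0, 1].
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b))
    stop("Overlap Coefficient undefined for an empty set")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Maximum Overlap Coefficient across all stringency pairs
#'
#' Because an inference set can expand or contract massively with stringency,
#' similarity between two methods is taken as the maximum Overlap Coefficient
#' over the Cartesian product of their stringency levels (empty levels
#' skipped).
#'
#' @param set1,set2 Gain-event tibbles with a `stringency` column; each needs
#'   at least one non-empty level.
#' @return A number in [0, 1]; symmetric in its arguments.
#' @export
max_overlap_coefficient <- function(set1, set2) {
  keys1 <- lapply(split(set1, set1$stringency), event_keys)
  keys2 <- lapply(split(set2, set2$stringency), event_keys)
  keys1 <- keys1[lengths(keys1) > 0]
  keys2 <- keys2[lengths(keys2) > 0]
  if (!length(keys1) || !length(keys2))
    stop("inference set has no non-empty stringency level")
  best <- 0
  for (ka in keys1) for (kb in keys2) {
    oc <- overlap_coefficient(ka, kb)
    if (oc > best) best <- oc
    if (best >= 1) return(1)
  }
  best
}

#' Distance matrix between inference sets (1 - max Overlap Coefficient)
#'
#' @param sets Named list (>= 2) of gain-event tibbles; names label the
#'   methods.
#' @return A symmetric matrix of class `hgt_dist` with zero diagonal.
#' @export
build_distance_matrix <- function(sets) {
  if (length(sets) < 2) stop("need at least two inference sets")
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("sets must carry unique non-empty names")
  n <- length(sets)
  d <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- 1 - max_overlap_coefficient(sets[[i]], sets[[j]])
  }
  structure(d, class = c("hgt_dist", class(d)))
}

#' @method tidy hgt_dist
#' @export
tidy.hgt_dist <- function(x, ...) {
  nm <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(method_a = nm[idx[, 1]], method_b = nm[idx[, 2]],
                 distance = x[idx])
}

#' UPGMA dendrogram of inference methods
#'
#' Standard unweighted average-linkage agglomeration: the closest pair of
#' clusters is merged at a node of height (their distance)/2, and distances
#' to the merged cluster are the size-weighted average of distances to its
#' parts. Ties are broken deterministically by the lexicographically smallest
#' pair of cluster names (a cluster is named after its lexicographically
#' first member).
#'
#' @param d A symmetric distance matrix with row/column names (e.g. an
#'   `hgt_dist` from [build_distance_matrix()]).
#' @return A list of class `hgt_upgma`: `$newick` (string with branch
#'   lengths), `$phy` (the corresponding [ape::phylo]), `$merges` (tibble of
#'   merge heights).
#' @export
upgma <- function(d) {
  d <- unclass(as.matrix(d))
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("distance matrix not symmetric")
  nm <- rownames(d)
  if (is.null(nm)) stop("distance matrix needs row names")
  n <- length(nm)
  if (n < 2) stop("need at least two methods")

  nwk <- nm
  name <- nm                # lexicographic representative per cluster
  size <- rep(1L, n)
  height <- rep(0, n)
  active <- rep(TRUE, n)
  merges <- list()

  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- NULL
    for (ii in seq_along(idx)) {
      for (jj in seq_along(idx)) {
        if (jj <= ii) next
        i <- idx[ii]; j <- idx[jj]
        pair_names <- sort(c(name[i], name[j]))
        cand <- list(i = i, j = j, dist = d[i, j], key = pair_names)
        if (is.null(best) || cand$dist < best$dist - 1e-15 ||
            (abs(cand$dist - best$dist) <= 1e-15 &&
             (cand$key[1] < best$key[1] ||
              (cand$key[1] == best$key[1] && cand$key[2] < best$key[2])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$dist / 2
    # lexicographically-first cluster written first for determinism
    ord <- if (name[i] <= name[j]) c(i, j) else c(j, i)
    nwk_new <- sprintf("(%s:%.10g,%s:%.10g)",
                       nwk[ord[1]], h - height[ord[1]],
                       nwk[ord[2]], h - height[ord[2]])
    merges[[step]] <- tibble::tibble(step = step, cluster_a = name[ord[1]],
                                     cluster_b = name[ord[2]], height = h)
    # size-weighted average distances to the merged cluster (kept in slot i)
    for (k in idx) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <- (size[i] * d[i, k] + size[j] * d[j, k]) /
        (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    height[i] <- h
    nwk[i] <- nwk_new
    name[i] <- min(name[i], name[j])
    active[j] <- FALSE
  }

  newick <- paste0(nwk[which(active)], ";")
  structure(list(newick = newick,
                 phy = ape::read.tree(text = newick),
                 merges = dplyr::bind_rows(merges)),
            class = "hgt_upgma")
}

#' @export
print.hgt_upgma <- function(x, ...) {
  cat("UPGMA dendrogram:", length(x$phy$tip.label), "methods\n")
  cat(x$newick, "\n")
  invisible(x)
}
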
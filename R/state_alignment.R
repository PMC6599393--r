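#' Extract per-state mean activation maps from a fitted model
#'
#' The emission mean vector of each latent state, interpreted as that state's
#' whole-brain activation pattern over parcels.
#'
#' @param params an [hmm_params] (or an `hmm_fit`, whose params are used).
#' @param group_key group label to attach, e.g. `"girl_ADHD"`.
#' @return object of class `state_maps`: list with `group_key`, `maps`
#'   (K x C matrix, row k = state k's mean map) and `state_ids`.
#' @export
extract_state_maps <- function(params, group_key) {
  if (inherits(params, "hmm_fit")) params <- params$params
  stopifnot(inherits(params, "hmm_params"))
  maps <- params$means
  rownames(maps) <- paste0("state_", seq_len(params$K))
  structure(list(group_key = as.character(group_key), maps = maps,
                 state_ids = seq_len(params$K)),
            class = "state_maps")
}

stack_maps <- function(maps_list) {
  stopifnot(length(maps_list) >= 1L,
            all(vapply(maps_list, inherits, logical(1), "state_maps")))
  C <- ncol(maps_list[[1L]]$maps)
  for (m in maps_list) if (ncol(m$maps) != C) stop("state maps disagree on channel count")
  X <- do.call(rbind, lapply(maps_list, `[[`, "maps"))
  meta <- do.call(rbind, lapply(maps_list, function(m)
    data.frame(group = m$group_key, state = m$state_ids, stringsAsFactors = FALSE)))
  rownames(X) <- paste(meta$group, meta$state, sep = ":")
  list(X = X, meta = meta)
}

#' Cluster state maps across groups by k-means
#'
#' Matches independently estimated latent states across the four group models
#' by running Euclidean k-means on the stacked mean activation maps. With K
#' states per group the expectation is that each of the k clusters contains
#' exactly one map per group; [validate_assignment()] checks this.
#'
#' @param maps_list list of `state_maps`, one per group.
#' @param k number of clusters (normally the per-group state count).
#' @param n_init number of k-means starts; the best by within-cluster sum of
#'   squares is kept.
#' @param seed integer seed for reproducible initialization.
#' @return object of class `cluster_assignment`: list with `entries`
#'   (data frame group, state, cluster), `centroids` (k x C), `inertia`
#'   (total within-cluster SS), `valid` flag, and `violations`.
#' @export
cluster_state_maps <- function(maps_list, k, n_init = 50L, seed = 1L) {
  st <- stack_maps(maps_list)
  n <- nrow(st$X)
  if (k > n) stop(sprintf("cannot form %d clusters from %d maps", k, n))
  if (k == n) {
    # exact k-means solution: one singleton cluster per map, zero inertia
    km <- list(cluster = seq_len(n), centers = st$X, tot.withinss = 0)
  } else {
    km <- with_seed(seed, tryCatch(
      kmeans(st$X, centers = k, nstart = n_init, iter.max = 100L),
      error = function(e) kmeans(st$X, centers = k, nstart = n_init,
                                 iter.max = 100L, algorithm = "Lloyd")))
  }
  entries <- st$meta
  entries$cluster <- as.integer(km$cluster)
  out <- structure(list(entries = entries, centroids = km$centers,
                        inertia = km$tot.withinss),
                   class = "cluster_assignment")
  rep <- validate_assignment(out)
  out$valid <- rep$valid
  out$violations <- rep$violations
  out
}

#' Validate a cross-group cluster assignment
#'
#' An assignment is valid when every cluster contains exactly one state map
#' from each group — the condition under which cluster labels define a
#' consistent cross-group state identity.
#'
#' @param assignment a `cluster_assignment`.
#' @return list with `valid` (logical) and `violations`: data frame of
#'   (cluster, group, count) rows where the count differs from one.
#' @export
validate_assignment <- function(assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  e <- assignment$entries
  groups <- unique(e$group)
  clusters <- sort(unique(e$cluster))
  tab <- table(factor(e$cluster, levels = clusters),
               factor(e$group, levels = groups))
  bad <- which(tab != 1L, arr.ind = TRUE)
  violations <- data.frame(
    cluster = clusters[bad[, 1L]],
    group = groups[bad[, 2L]],
    count = as.integer(tab[bad]),
    stringsAsFactors = FALSE)
  violations <- violations[order(violations$cluster, violations$group), , drop = FALSE]
  rownames(violations) <- NULL
  list(valid = nrow(violations) == 0L, violations = violations)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d maps -> %d clusters, inertia=%.4f, valid=%s\n",
              nrow(x$entries), nrow(x$centroids), x$inertia,
              if (isTRUE(x$valid)) "yes" else "NO"))
  invisible(x)
}

#' Consensus maps and per-group state relabeling
#'
#' Averages the four member maps of each valid cluster into a consensus map,
#' and derives, for every group, the relabeling from its local state indices
#' to consensus labels. Consensus labels are ordered by descending total
#' absolute activation — an arbitrary but deterministic convention, since
#' state numbering itself carries no meaning.
#'
#' @param maps_list list of `state_maps` (the ones that were clustered).
#' @param assignment a valid `cluster_assignment`.
#' @return list with `consensus` (K x C matrix, row = consensus state),
#'   `relabeling` (named list: per group an integer vector mapping local state
#'   index to consensus label), and `cluster_order` (consensus label of each
#'   original cluster id).
#' @export
consensus_maps <- function(maps_list, assignment) {
  rep <- validate_assignment(assignment)
  if (!rep$valid)
    stop("cluster assignment is not valid (see validate_assignment()); ",
         nrow(rep$violations), " violation(s)")
  st <- stack_maps(maps_list)
  e <- assignment$entries
  clusters <- sort(unique(e$cluster))
  raw <- t(vapply(clusters, function(cl)
    colMeans(st$X[e$cluster == cl, , drop = FALSE]), numeric(ncol(st$X))))
  ord <- order(-rowSums(abs(raw)), clusters)
  consensus <- raw[ord, , drop = FALSE]
  rownames(consensus) <- paste0("state_", seq_along(clusters))
  colnames(consensus) <- colnames(st$X)
  cluster_order <- integer(length(clusters))
  cluster_order[match(clusters[ord], clusters)] <- seq_along(clusters)
  names(cluster_order) <- as.character(clusters)
  relabeling <- lapply(split(e, e$group), function(g) {
    g <- g[order(g$state), , drop = FALSE]
    out <- cluster_order[as.character(g$cluster)]
    names(out) <- NULL
    out
  })
  relabeling <- relabeling[unique(e$group)]
  list(consensus = consensus, relabeling = relabeling, cluster_order = cluster_order)
}

#' Apply (or invert) a group's state relabeling to a label vector
#'
#' @param labels integer vector of local state labels.
#' @param map integer vector mapping local state index to consensus label.
#' @param invert apply the inverse mapping (consensus back to local).
#' @return relabeled integer vector.
#' @export
apply_relabeling <- function(labels, map, invert = FALSE) {
  stopifnot(!anyDuplicated(map), all(sort(map) == seq_along(map)))
  if (invert) map <- order(map)
  map[labels]
}
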
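# Faunal beta diversity among provinces: species assignment to rectangular
# province geometries, Sorenson similarity, exclusion of depauperate
# provinces, UPGMA clustering and Newick export.

#' Define rectangular provinces over a synthetic world
#'
#' Splits each realm's longitudinal sector into latitudinal bands, giving a
#' set of box provinces labelled by parent realm — the synthetic analogue of
#' marine eco-provinces.
#'
#' @param config a [world_config()].
#' @param band_height latitudinal height of each province (degrees).
#' @return data.frame `province_id, name, realm, lat_min, lat_max, lon_min,
#'   lon_max`.
#' @export
make_provinces <- function(config, band_height = 30) {
  edges <- seq(config$lat_min, config$lat_max, by = band_height)
  if (edges[length(edges)] < config$lat_max) {
    edges <- c(edges, config$lat_max)
  }
  rows <- list()
  for (r in realm_names) {
    rng <- realm_lon_range(r, config)
    for (i in seq_len(length(edges) - 1)) {
      rows[[length(rows) + 1]] <- data.frame(
        realm = r, lat_min = edges[i], lat_max = edges[i + 1],
        lon_min = rng[1], lon_max = rng[2], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$province_id <- sprintf("P%02d", seq_len(nrow(out)))
  out$name <- sprintf("%s_%g_%g", out$realm, out$lat_min, out$lat_max)
  out[, c("province_id", "name", "realm", "lat_min", "lat_max",
          "lon_min", "lon_max")]
}

#' Assign species to provinces
#'
#' A species belongs to a province if it has at least one record inside the
#' province's rectangle at depth shallower than `depth_limit`, or if the
#' catalogue names the province for that species (via an optional
#' `catalogue_provinces` mapping). Records falling in no province are
#' counted and reported via the `unassigned` attribute.
#'
#' @param records occurrence data.frame with resolved depths.
#' @param provinces data.frame as from [make_provinces()].
#' @param depth_limit depth cutoff in metres (default 200, the shallow
#'   stratum).
#' @param catalogue_provinces optional named list mapping `province_id` to
#'   character vectors of species known from descriptive ranges.
#' @return named list of species-id character vectors, one per province, in
#'   province order; attribute `unassigned` holds the count of shallow
#'   records outside every province.
#' @export
assign_species <- function(records, provinces, depth_limit = 200,
                           catalogue_provinces = NULL) {
  shallow <- records[!is.na(records$depth_m) &
                       records$depth_m < depth_limit, , drop = FALSE]
  sets <- vector("list", nrow(provinces))
  names(sets) <- provinces$province_id
  assigned <- rep(FALSE, nrow(shallow))
  for (p in seq_len(nrow(provinces))) {
    inside <- shallow$decimalLatitude >= provinces$lat_min[p] &
      shallow$decimalLatitude < provinces$lat_max[p] &
      shallow$decimalLongitude >= provinces$lon_min[p] &
      shallow$decimalLongitude < provinces$lon_max[p]
    assigned <- assigned | inside
    sets[[p]] <- sort(unique(shallow$species_id[inside]))
    extra <- catalogue_provinces[[provinces$province_id[p]]]
    if (!is.null(extra)) sets[[p]] <- sort(unique(c(sets[[p]], extra)))
  }
  n_un <- sum(!assigned)
  if (n_un > 0) {
    message(n_un, " shallow record(s) fell inside no province")
  }
  attr(sets, "unassigned") <- n_un
  sets
}

#' Sorenson similarity between two faunas
#'
#' `100 * 2|A n B| / (2|A n B| + |A \\ B| + |B \\ A|)`, the percentage of
#' shared species weighted towards the intersection.
#'
#' @param a,b character vectors of species ids (duplicates ignored).
#' @return similarity percentage in `[0, 100]`.
#' @export
sorenson <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) {
    stop("Sorenson similarity is undefined for two empty faunas")
  }
  both <- length(intersect(a, b))
  only_a <- length(setdiff(a, b))
  only_b <- length(setdiff(b, a))
  100 * (2 * both) / (2 * both + only_a + only_b)
}

#' Pairwise Sorenson similarity matrix
#'
#' @param assemblages named list of species-id vectors (>= 2 provinces).
#' @return symmetric matrix of percentages with 100 on the diagonal, class
#'   `similarity_matrix`.
#' @export
similarity_matrix <- function(assemblages) {
  k <- length(assemblages)
  if (k < 2) stop("need at least two provinces")
  s <- matrix(100, k, k, dimnames = list(names(assemblages),
                                         names(assemblages)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s[i, j] <- s[j, i] <- sorenson(assemblages[[i]], assemblages[[j]])
    }
  }
  structure(s, class = c("similarity_matrix", "matrix"))
}

#' Exclude species-poor provinces
#'
#' Removes provinces with fewer than `min_species` species (island faunas
#' dominated by a handful of endemics cluster unstably and are excluded
#' before building the dendrogram); removals are messaged.
#'
#' @param assemblages named list of species-id vectors.
#' @param min_species minimum fauna size to retain.
#' @return filtered list.
#' @export
exclude_sparse <- function(assemblages, min_species = 1) {
  sizes <- vapply(assemblages, function(x) length(unique(x)), integer(1))
  drop <- sizes < min_species
  if (any(drop)) {
    message("excluding ", sum(drop), " sparse province(s): ",
            paste(names(assemblages)[drop], collapse = ", "))
  }
  assemblages[!drop]
}

#' UPGMA clustering of a dissimilarity matrix
#'
#' Average-linkage agglomerative clustering: repeatedly merges the pair with
#' the minimal average distance at height D/2, updating distances by
#' size-weighted averages. Ties are broken by the lowest (row, column)
#' index pair, making the result deterministic.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal (e.g.
#'   `100 - similarity_matrix`).
#' @return object of class `upgma_tree`: hclust-style `merge` matrix,
#'   `height` (merge heights, D/2 units) and `labels`.
#' @export
upgma <- function(d) {
  d <- unclass(as.matrix(d))
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("dissimilarity matrix must be symmetric")
  }
  if (any(abs(diag(d)) > 1e-8)) stop("dissimilarity diagonal must be zero")
  n <- nrow(d)
  labels <- rownames(d) %||% paste0("L", seq_len(n))
  if (n == 1) {
    return(structure(list(merge = matrix(numeric(0), 0, 2),
                          height = numeric(0), labels = labels,
                          n = 1L), class = "upgma_tree"))
  }
  size <- rep(1L, n)
  id <- -seq_len(n)      # negative = leaf, positive = merge row
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  work <- d
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    act <- which(active)
    for (ii in seq_along(act)[-length(act)]) {
      for (jj in (ii + 1):length(act)) {
        i <- act[ii]; j <- act[jj]
        if (work[i, j] < best_d - 1e-12) {
          best_d <- work[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- c(id[i], id[j])
    height[step] <- best_d / 2
    # size-weighted average update into slot i
    for (k in act) {
      if (k != i && k != j) {
        work[i, k] <- work[k, i] <-
          (size[i] * work[i, k] + size[j] * work[j, k]) / (size[i] + size[j])
      }
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    id[i] <- step
  }
  structure(list(merge = merge, height = height, labels = labels,
                 n = as.integer(n)), class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("upgma_tree: %d leaves, root height %g\n", x$n,
              if (length(x$height)) max(x$height) else 0))
  invisible(x)
}

# leaves under a merge-tree node (hclust convention)
node_leaves <- function(tree, node) {
  if (node < 0) return(-node)
  c(node_leaves(tree, tree$merge[node, 1]),
    node_leaves(tree, tree$merge[node, 2]))
}

#' Cophenetic distance matrix of a UPGMA tree
#'
#' Distance between two leaves is twice the height of their lowest common
#' merge (heights are D/2, so cophenetic distances are on the original
#' dissimilarity scale).
#'
#' @param tree an `upgma_tree`.
#' @return symmetric matrix of cophenetic distances.
#' @export
cophenetic_matrix <- function(tree) {
  n <- tree$n
  m <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  for (step in seq_len(nrow(tree$merge))) {
    left <- node_leaves(tree, tree$merge[step, 1])
    right <- node_leaves(tree, tree$merge[step, 2])
    m[left, right] <- 2 * tree$height[step]
    m[right, left] <- 2 * tree$height[step]
  }
  m
}

#' Cut a UPGMA tree into k groups
#'
#' @param tree an `upgma_tree`.
#' @param k number of groups.
#' @return named integer vector of group memberships over leaves.
#' @export
cut_upgma <- function(tree, k) {
  stopifnot(k >= 1, k <= tree$n)
  keep <- seq_len(tree$n - k)       # merges applied, highest k-1 undone
  groups <- -seq_len(tree$n)
  memb <- seq_len(tree$n)
  for (step in keep) {
    left <- node_leaves(tree, tree$merge[step, 1])
    right <- node_leaves(tree, tree$merge[step, 2])
    memb[c(left, right)] <- min(memb[c(left, right)])
  }
  out <- as.integer(factor(memb))
  names(out) <- tree$labels
  out
}

#' Newick serialisation of a UPGMA tree
#'
#' Branch lengths are height differences between parent and child merges
#' (leaves hang from their first merge at its full height), so the parsed
#' tree's cophenetic distances reproduce [cophenetic_matrix()].
#'
#' @param tree an `upgma_tree`.
#' @return a Newick string terminated by `;`.
#' @export
to_newick <- function(tree) {
  if (tree$n == 1) return(paste0(tree$labels[1], ";"))
  fmt <- function(node, parent_h) {
    if (node < 0) {
      sprintf("%s:%.12g", tree$labels[-node], parent_h)
    } else {
      h <- tree$height[node]
      sprintf("(%s,%s):%.12g", fmt(tree$merge[node, 1], h),
              fmt(tree$merge[node, 2], h), parent_h - h)
    }
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  sprintf("(%s,%s);", fmt(tree$merge[root, 1], h),
          fmt(tree$merge[root, 2], h))
}
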
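#' Channel adjacency from electrode geometry
#'
#' Channels are projected with an azimuthal-equidistant projection about the
#' vertex and triangulated (Delaunay, by direct empty-circumcircle search --
#' cheap at cap sizes); triangulation edges longer than 1.5 x the median
#' edge are pruned so the mesh does not bridge across the head. If the
#' triangulation degenerates (collinear layouts, < 4 channels) the adjacency
#' falls back to k-nearest neighbours (k = 4). Channels left with fewer than
#' 2 neighbours are topped up with their nearest channels.
#'
#' @param montage an `mmn_montage`
#' @return object of class `channel_adjacency`: `names`, `neighbors`
#'   (list of integer vectors), `matrix` (symmetric logical)
#' @export
build_adjacency <- function(montage) {
  nch <- nrow(montage)
  if (nch < 2) stopf("invalid argument: need at least 2 channels")
  pos <- montage_positions(montage)
  # azimuthal-equidistant projection about the vertex (0, 0, 1)
  theta <- acos(pmin(1, pmax(-1, pos[, 3])))
  rho <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  px <- ifelse(rho > 1e-12, theta * pos[, 1] / rho, 0)
  py <- ifelse(rho > 1e-12, theta * pos[, 2] / rho, 0)
  pts <- cbind(px, py)

  A <- matrix(FALSE, nch, nch)
  if (nch >= 4) {
    tri <- delaunay_edges(pts)
    if (!is.null(tri)) {
      elen <- sqrt(rowSums((pts[tri[, 1], , drop = FALSE] -
                            pts[tri[, 2], , drop = FALSE])^2))
      tri <- tri[elen <= 1.5 * median(elen), , drop = FALSE]
      A[tri] <- TRUE
      A[tri[, 2:1, drop = FALSE]] <- TRUE
    }
  }
  if (!any(A)) {            # fallback: k-nearest
    k <- min(4, nch - 1)
    d <- as.matrix(stats::dist(pts))
    for (j in seq_len(nch)) {
      nb <- order(d[j, ])[2:(k + 1)]
      A[j, nb] <- TRUE
      A[nb, j] <- TRUE
    }
  }
  # top up isolated / degree-1 channels with nearest neighbours
  d <- as.matrix(stats::dist(pts))
  for (j in which(rowSums(A) < 2)) {
    nb <- order(d[j, ])[2:min(3, nch)]
    A[j, nb] <- TRUE
    A[nb, j] <- TRUE
  }
  diag(A) <- FALSE
  dimnames(A) <- list(montage$name, montage$name)
  structure(list(names = montage$name,
                 neighbors = lapply(seq_len(nch), function(j) which(A[j, ])),
                 matrix = A),
            class = "channel_adjacency")
}

# All Delaunay edges of a 2-D point set by empty-circumcircle test over
# point triples. Returns a 2-column index matrix, or NULL when degenerate.
delaunay_edges <- function(pts) {
  n <- nrow(pts)
  combs <- utils::combn(n, 3)
  edges <- matrix(integer(0), 0, 2)
  found <- FALSE
  for (c_i in seq_len(ncol(combs))) {
    i <- combs[1, c_i]; j <- combs[2, c_i]; k <- combs[3, c_i]
    ax <- pts[i, 1]; ay <- pts[i, 2]
    bx <- pts[j, 1]; by <- pts[j, 2]
    cx <- pts[k, 1]; cy <- pts[k, 2]
    dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(dd) < 1e-12) next                       # collinear triple
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / dd
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / dd
    r2 <- (ax - ux)^2 + (ay - uy)^2
    d2 <- (pts[, 1] - ux)^2 + (pts[, 2] - uy)^2
    d2[c(i, j, k)] <- Inf
    if (all(d2 > r2 * (1 - 1e-9))) {
      found <- TRUE
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
    }
  }
  if (!found) return(NULL)
  unique(edges)
}

#' Spatio-temporal cluster-based permutation test
#'
#' Tests the deviant-minus-standard difference against zero jointly over
#' channels and time. Per channel x time point, a paired t statistic is
#' computed across subjects; points exceeding the two-tailed critical value
#' (`cluster_alpha`, df = n - 1) are clustered under spatio-temporal
#' connectivity (spatial neighbours at the same sample, same channel at
#' adjacent samples), positive and negative t separately, and each cluster
#' is scored by its summed t ("maxsum"). The null distribution is built by
#' randomly exchanging condition labels within subject (a sign flip of each
#' subject's difference), recording per permutation the most extreme signed
#' cluster mass. A cluster is significant when its mass falls below the
#' 2.5th or above the 97.5th percentile of that distribution (for
#' `alpha = 0.05`); Monte-Carlo p-values carry the (b + 1)/(B + 1)
#' correction.
#'
#' @param dev_evokeds,std_evokeds matched per-subject lists of `evoked`
#'   objects (or plain channels x time matrices)
#' @param adjacency a [build_adjacency()] result matching the channel order
#' @param alpha familywise alpha for the percentile rule (default 0.05)
#' @param n_perm number of permutations (default 2000; < 100 warns)
#' @param cluster_alpha two-tailed p for the cluster-forming threshold
#' @param seed integer seed for the sign flips
#' @return object of class `cluster_test`: `clusters` (list with `members`,
#'   `mass`, `sign`, `p_mc`, `significant`), `t_obs` (channels x time),
#'   `null_extremes`, `crit` (the percentile bounds), `n_subjects`
#' @export
cluster_permutation_test <- function(dev_evokeds, std_evokeds, adjacency,
                                     alpha = 0.05, n_perm = 2000,
                                     cluster_alpha = 0.05, seed = 1L) {
  n <- length(dev_evokeds)
  if (n < 5 || length(std_evokeds) != n)
    stopf("invalid argument: need >= 5 matched evoked pairs")
  if (n_perm < 100) warning("n_perm < 100: permutation p-values are coarse")
  as_mat <- function(e) if (inherits(e, "evoked")) e$data else e
  d1 <- as_mat(dev_evokeds[[1]])
  nch <- nrow(d1); ntime <- ncol(d1)
  if (nch != length(adjacency$names))
    stopf("invalid argument: adjacency does not match the channel count")
  P <- nch * ntime
  D <- matrix(NA_real_, n, P)
  for (i in seq_len(n)) {
    di <- as_mat(dev_evokeds[[i]]) - as_mat(std_evokeds[[i]])
    D[i, ] <- as.vector(di)          # column-major: ch fastest
  }
  mu <- colMeans(D)
  ss <- colSums(D^2)
  vv <- pmax(0, (ss - n * mu^2) / (n - 1))
  se <- sqrt(vv / n)
  t_obs <- ifelse(se > 0, mu / se, 0)
  tcrit <- qt(1 - cluster_alpha / 2, n - 1)

  nb <- adjacency$neighbors
  lab_pos <- cpp_label_clusters(t_obs > tcrit, nb, nch, ntime)
  lab_neg <- cpp_label_clusters(t_obs < -tcrit, nb, nch, ntime)

  collect <- function(labels, sgn) {
    ncl <- max(labels)
    if (!ncl) return(list())
    lapply(seq_len(ncl), function(cl) {
      m <- which(labels == cl)
      list(members = data.frame(channel = adjacency$names[(m - 1) %% nch + 1],
                                time_index = (m - 1) %/% nch + 1),
           index = m,
           mass = sum(t_obs[m]),
           sign = sgn)
    })
  }
  clusters <- c(collect(lab_pos, "+"), collect(lab_neg, "-"))

  # null distribution: within-subject sign flips
  S <- with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                              n_perm, n))
  M <- (S %*% D) / n
  Vp <- (rep(1, n_perm) %o% ss - n * M^2) / (n - 1)
  Tp <- M / sqrt(pmax(Vp, 0) / n)
  Tp[!is.finite(Tp)] <- 0
  ext <- cpp_perm_extremes(Tp, tcrit, nb, nch, ntime)
  signed_extreme <- ifelse(ext[, 1] >= -ext[, 2], ext[, 1], ext[, 2])
  crit <- quantile(signed_extreme, c(alpha / 2, 1 - alpha / 2), names = FALSE)

  for (i in seq_along(clusters)) {
    m <- clusters[[i]]$mass
    clusters[[i]]$p_mc <- (1 + sum(abs(signed_extreme) >= abs(m))) / (n_perm + 1)
    clusters[[i]]$significant <- if (clusters[[i]]$sign == "+")
      m > crit[2] else m < crit[1]
  }
  structure(list(clusters = clusters,
                 t_obs = matrix(t_obs, nch, ntime,
                                dimnames = list(adjacency$names, NULL)),
                 null_extremes = signed_extreme, crit = crit,
                 n_subjects = n, n_perm = n_perm, alpha = alpha),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  ns <- sum(vapply(x$clusters, `[[`, logical(1), "significant"))
  cat(sprintf("<cluster_test> %d subjects, %d permutations: %d cluster(s), %d significant\n",
              x$n_subjects, x$n_perm, length(x$clusters), ns))
  ord <- order(-abs(vapply(x$clusters, `[[`, numeric(1), "mass")))
  for (cl in x$clusters[utils::head(ord, 10)])
    cat(sprintf("  %s mass %.1f, %d points, p = %.4f%s\n", cl$sign, cl$mass,
                nrow(cl$members), cl$p_mc,
                if (cl$significant) " *" else ""))
  if (length(x$clusters) > 10)
    cat(sprintf("  ... and %d smaller clusters\n", length(x$clusters) - 10))
  invisible(x)
}
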
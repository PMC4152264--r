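#' Number of coarse-grained spheres for a protein of given molecular weight
#'
#' Piecewise-constant map from molecular weight to cluster count: one sphere
#' below the first boundary, up to five above the last. Boundaries are
#' half-open \code{[lo, hi)}, so a protein sitting exactly on a boundary
#' belongs to the next (larger) band: 14 kDa maps to 3 spheres, 32 kDa to 5.
#'
#' @param mw molecular weight, kDa (vectorized).
#' @param boundaries increasing band boundaries, kDa.
#' @return integer cluster count in \code{1..(length(boundaries)+1)}.
#' @export
#' @examples
#' clusterCountForMW(c(2, 5, 14, 23, 32, 50))
clusterCountForMW <- function(mw, boundaries = c(5, 14, 23, 32)) {
  if (any(!is.finite(mw)) || any(mw <= 0))
    stop("molecular weight must be positive and finite")
  findInterval(mw, boundaries) + 1L
}

#' k-means clustering of C-alpha coordinates
#'
#' Lloyd's algorithm (via \code{stats::kmeans}) started from k-means++ seeds,
#' repeated \code{nStart} times; the restart with the lowest total
#' within-cluster sum of squares wins, ties broken by the earliest restart.
#' Deterministic for a fixed \code{seed}.
#'
#' @param coords numeric matrix (residues x 3) of C-alpha coordinates.
#' @param k number of clusters, \code{1 <= k <= nrow(coords)}.
#' @param seed integer RNG seed.
#' @param nStart number of k-means++ restarts.
#' @return list with \code{labels} (integer per residue) and \code{centers}
#'   (k x 3 matrix of per-cluster means).
#' @export
kmeansCalpha <- function(coords, k, seed = 1L, nStart = 50L) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  if (k < 1L || k > n) stop("need 1 <= k <= number of residues")
  if (k == 1L) {
    return(list(labels = rep(1L, n),
                centers = matrix(colMeans(coords), 1, 3)))
  }
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  best <- NULL
  for (s in seq_len(nStart)) {
    init <- .kmeanspp_init(coords, k)
    fit <- suppressWarnings(
      kmeans(coords, centers = init, iter.max = 100L, algorithm = "Lloyd"))
    if (any(fit$size == 0)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss - 1e-12) best <- fit
  }
  if (is.null(best)) stop("k-means failed to produce k non-empty clusters")
  # relabel clusters by first appearance so labels are order-stable
  map <- integer(k)
  map[unique(best$cluster)] <- seq_len(k)
  labels <- map[best$cluster]
  centers <- matrix(0, k, 3)
  for (c in seq_len(k)) centers[c, ] <- colMeans(coords[labels == c, , drop = FALSE])
  list(labels = as.integer(labels), centers = centers)
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center.
.kmeanspp_init <- function(coords, k) {
  n <- nrow(coords)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums((coords - matrix(coords[idx[1], ], n, 3, byrow = TRUE))^2)
  for (c in seq_len(k - 1L)) {
    if (all(d2 <= 0)) {
      idx[c + 1L] <- sample.int(n, 1L)
    } else {
      idx[c + 1L] <- sample.int(n, 1L, prob = d2 / sum(d2))
    }
    nd <- rowSums((coords - matrix(coords[idx[c + 1L], ], n, 3, byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  coords[idx, , drop = FALSE] + matrix(rnorm(3 * k, sd = 1e-9), k, 3)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Volume of a union of spheres
#'
#' Exact for one sphere and for two (spherical-lens formula). For three or
#' more spheres the default is pairwise inclusion-exclusion (sum of sphere
#' volumes minus all pairwise intersections); triple and higher-order
#' overlaps are ignored, which slightly underestimates the union when three
#' spheres share a region -- rare for chain-like cluster geometries. A
#' Monte-Carlo estimator with a stated sample count is available as a
#' cross-check or for configurations with substantial triple overlap.
#'
#' @param centers numeric matrix (n x 3), Angstrom.
#' @param radii sphere radii, Angstrom.
#' @param method "auto" (exact for n <= 2, pairwise otherwise), "pairwise",
#'   or "mc".
#' @param nSamples Monte-Carlo sample count (method = "mc").
#' @param seed RNG seed for method = "mc".
#' @return union volume, Angstrom^3.
#' @export
unionVolume <- function(centers, radii, method = c("auto", "pairwise", "mc"),
                        nSamples = 1e6, seed = 1L) {
  method <- match.arg(method)
  centers <- matrix(as.numeric(centers), ncol = 3)
  n <- nrow(centers)
  if (length(radii) != n || any(radii <= 0)) stop("radii must be positive, one per center")
  if (method == "mc") return(.union_volume_mc(centers, radii, nSamples, seed))
  vols <- 4 / 3 * pi * radii^3
  if (n == 1L) return(vols)
  tot <- sum(vols)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- sqrt(sum((centers[i, ] - centers[j, ])^2))
      tot <- tot - .lens_volume(d, radii[i], radii[j])
    }
  }
  tot
}

# intersection volume of two spheres
.lens_volume <- function(d, r1, r2) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(4 / 3 * pi * min(r1, r2)^3)
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
}

.union_volume_mc <- function(centers, radii, nSamples, seed) {
  lo <- apply(centers - radii, 2, min)
  hi <- apply(centers + radii, 2, max)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  n <- as.integer(nSamples)
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]), runif(n, lo[3], hi[3]))
  inside <- rep(FALSE, n)
  for (i in seq_len(nrow(centers))) {
    d2 <- (pts[, 1] - centers[i, 1])^2 + (pts[, 2] - centers[i, 2])^2 +
      (pts[, 3] - centers[i, 3])^2
    inside <- inside | (d2 <= radii[i]^2)
  }
  mean(inside) * prod(hi - lo)
}

#' Assign sphere radii so the union volume matches an all-atom target
#'
#' Radii are proportional to a power of the residue count of each cluster
#' (default cube root, so sphere volume is proportional to residue count),
#' with a single global scale factor solved so that the union volume of the
#' placed spheres equals \code{targetVolume} to 1e-6 relative tolerance,
#' overlaps accounted for.
#'
#' @param labels cluster label per residue (from \code{\link{kmeansCalpha}}).
#' @param centers cluster centers (k x 3), Angstrom.
#' @param targetVolume all-atom reference volume, Angstrom^3.
#' @param proportionality "volume" for radius proportional to n^(1/3)
#'   (default), "linear" for radius proportional to n.
#' @return numeric radii, Angstrom, ordered like the cluster centers.
#' @export
assignRadii <- function(labels, centers, targetVolume,
                        proportionality = c("volume", "linear")) {
  proportionality <- match.arg(proportionality)
  if (targetVolume <= 0) stop("targetVolume must be > 0")
  centers <- matrix(as.numeric(centers), ncol = 3)
  k <- nrow(centers)
  nres <- tabulate(labels, nbins = k)
  if (any(nres == 0)) stop("every cluster must be non-empty")
  base <- if (proportionality == "volume") nres^(1 / 3) else as.numeric(nres)
  f <- function(s) unionVolume(centers, s * base) - targetVolume
  # bracket: disjoint upper bound gives union <= sum, so start there and grow
  sHi <- (targetVolume / (4 / 3 * pi * sum(base^3)))^(1 / 3)
  root <- tryCatch(
    uniroot(f, lower = 1e-8, upper = 2 * sHi, extendInt = "upX",
            tol = 1e-10 * sHi, maxiter = 200L),
    error = function(e) stop("model-build error: cannot scale spheres to the target volume (", conditionMessage(e), ")")
  )
  r <- root$root * base
  if (abs(unionVolume(centers, r) - targetVolume) > 1e-6 * targetVolume)
    stop("model-build error: union volume did not converge to target")
  r
}

#' All-pair bonded topology from reference sphere centers
#'
#' Bonds connect every unordered pair of spheres with equilibrium length
#' equal to the reference distance. Angles cover every vertex-distinct triple
#' (one angle per vertex per unordered pair of partners), equilibrium values
#' from the reference frame. A one-sphere protein has empty topology.
#'
#' @param centers numeric matrix (n x 3), Angstrom.
#' @return list with \code{bonds} (m x 2), \code{bondLengths}, \code{angles}
#'   (q x 3, columns i, vertex, k) and \code{angleValues} (radians).
#' @export
buildTopology <- function(centers) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  n <- nrow(centers)
  if (n < 1L) stop("need at least one sphere")
  if (n == 1L) {
    return(list(bonds = matrix(integer(), 0, 2), bondLengths = numeric(),
                angles = matrix(integer(), 0, 3), angleValues = numeric()))
  }
  pr <- t(utils::combn(n, 2))
  bl <- sqrt(rowSums((centers[pr[, 1], , drop = FALSE] -
                      centers[pr[, 2], , drop = FALSE])^2))
  angles <- matrix(integer(), 0, 3)
  av <- numeric()
  if (n >= 3L) {
    for (v in seq_len(n)) {
      others <- setdiff(seq_len(n), v)
      pairs <- t(utils::combn(others, 2))
      for (p in seq_len(nrow(pairs))) {
        i <- pairs[p, 1]; k <- pairs[p, 2]
        u <- centers[i, ] - centers[v, ]
        w <- centers[k, ] - centers[v, ]
        ct <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
        angles <- rbind(angles, c(i, v, k))
        av <- c(av, acos(max(-1, min(1, ct))))
      }
    }
  }
  list(bonds = pr, bondLengths = bl,
       angles = matrix(as.integer(angles), ncol = 3), angleValues = av)
}

#' Build a coarse-grained protein from C-alpha coordinates
#'
#' Clusters the residues with k-means (k from the molecular weight unless
#' given), places one sphere per cluster at the cluster mean, sizes the
#' spheres so that radius follows the chosen proportionality to residue
#' count and the union volume matches the all-atom reference volume, and
#' records the all-pair bonded topology of the reference geometry.
#'
#' The reference volume defaults to MW x 1.21 A^3/Da (a standard protein
#' partial specific volume) when only the molecular weight is known.
#'
#' @param coords C-alpha coordinate matrix (residues x 3), Angstrom.
#' @param molecularWeight kDa; if missing, estimated as 0.110 kDa per residue.
#' @param proteinId identifier string.
#' @param copyNumber copies in the box.
#' @param tracer logical tracer flag.
#' @param k cluster count override.
#' @param targetVolume reference volume override, Angstrom^3.
#' @param proportionality see \code{\link{assignRadii}}.
#' @param seed k-means seed.
#' @return a \code{\link{CGProtein-class}} object.
#' @export
buildCGProtein <- function(coords, molecularWeight = NULL, proteinId = "protein",
                           copyNumber = 1L, tracer = FALSE, k = NULL,
                           targetVolume = NULL,
                           proportionality = c("volume", "linear"),
                           seed = 1L) {
  proportionality <- match.arg(proportionality)
  coords <- as.matrix(coords)
  if (is.null(molecularWeight)) molecularWeight <- 0.110 * nrow(coords)
  if (is.null(k)) k <- clusterCountForMW(molecularWeight)
  k <- min(k, nrow(coords))
  if (is.null(targetVolume)) targetVolume <- molecularWeight * 1000 * 1.21
  km <- kmeansCalpha(coords, k, seed = seed)
  radii <- assignRadii(km$labels, km$centers, targetVolume,
                       proportionality = proportionality)
  topo <- buildTopology(km$centers)
  new("CGProtein", proteinId = proteinId, centers = km$centers, radii = radii,
      bonds = topo$bonds, bondLengths = topo$bondLengths,
      angles = topo$angles, angleValues = topo$angleValues,
      molecularWeight = molecularWeight, copyNumber = as.integer(copyNumber),
      tracer = isTRUE(tracer))
}

#' Synthetic coarse-grained protein fixture
#'
#' Generates a connected, protein-like cluster of 1--5 spheres with radii in
#' roughly the 10--30 Angstrom range, suitable as a stand-in for PDB-derived
#' models in tests and synthetic boxes. Centers are laid down as a random
#' chain with neighbor spacing slightly below the sum of radii so the
#' cluster is connected; topology is the standard all-pair/all-triple set
#' computed from the generated reference geometry. Deterministic per seed.
#'
#' @param nSpheres 1 to 5.
#' @param sizeScale multiplies all lengths (default 1).
#' @param seed integer RNG seed.
#' @param proteinId identifier.
#' @param copyNumber copies in the box.
#' @param tracer logical tracer flag.
#' @return a \code{\link{CGProtein-class}} object.
#' @export
makeSyntheticProtein <- function(nSpheres, sizeScale = 1, seed = 1L,
                                 proteinId = sprintf("syn%02d", seed),
                                 copyNumber = 1L, tracer = FALSE) {
  if (nSpheres < 1L || nSpheres > 5L) stop("nSpheres must be in 1..5")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  radii <- runif(nSpheres, 10, 30) * sizeScale
  centers <- matrix(0, nSpheres, 3)
  if (nSpheres > 1L) {
    for (i in 2:nSpheres) {
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      gap <- runif(1, 0.7, 0.95) * (radii[i - 1] + radii[i])
      centers[i, ] <- centers[i - 1, ] + gap * dir
    }
  }
  mw <- sum(4 / 3 * pi * radii^3) / (1000 * 1.21)  # consistent mass proxy
  topo <- buildTopology(centers)
  new("CGProtein", proteinId = proteinId, centers = centers, radii = radii,
      bonds = topo$bonds, bondLengths = topo$bondLengths,
      angles = topo$angles, angleValues = topo$angleValues,
      molecularWeight = mw, copyNumber = as.integer(copyNumber),
      tracer = isTRUE(tracer))
}

# uniform random rotation matrix (quaternion method)
.random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Assemble a periodic crowded box from coarse-grained proteins
#'
#' Each copy of each protein is inserted at a uniformly random position with
#' a uniformly random orientation; a candidate placement is accepted when no
#' inter-protein sphere pair overlaps deeper than \code{overlapTol} under the
#' minimum-image convention. If random insertion fails after
#' \code{maxAttempts} tries for a molecule (dense packings), the box can be
#' completed in relaxation mode: remaining molecules are inserted at the
#' least-overlapping candidate found and the whole box is then relaxed by
#' steepest descent on the repulsive energy until no overlap exceeds
#' \code{overlapTol}. Deterministic for a fixed seed.
#'
#' @param proteins list of \code{\link{CGProtein-class}} objects (their
#'   \code{copyNumber} slots set the number of copies placed).
#' @param boxLength cubic box edge, Angstrom.
#' @param seed integer RNG seed.
#' @param overlapTol maximum tolerated overlap depth, Angstrom.
#' @param maxAttempts random insertion attempts per molecule.
#' @param relax "auto" (relax only if insertion fails), "never" (error
#'   instead), or "always".
#' @return a \code{\link{SystemState-class}} object; molecule membership and
#'   the global bonded topology are recorded.
#' @export
assembleBox <- function(proteins, boxLength, seed = 1L, overlapTol = 0.5,
                        maxAttempts = 1e5, relax = c("auto", "never", "always")) {
  relax <- match.arg(relax)
  if (length(proteins) == 0) {
    return(new("SystemState", boxLength = boxLength,
               positions = matrix(numeric(), 0, 3), radii = numeric(),
               molecule = integer(), proteinId = character(), D0 = numeric(),
               frozen = logical(), bonds = matrix(integer(), 0, 2),
               bondLengths = numeric(), angles = matrix(integer(), 0, 3),
               angleValues = numeric()))
  }
  maxR <- max(unlist(lapply(proteins, function(p) p@radii)))
  if (boxLength <= 2 * maxR) stop("boxLength must exceed twice the largest sphere radius")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))

  pos <- NULL; rad <- numeric(); molv <- integer(); pid <- character()
  bonds <- NULL; bl <- numeric(); angles <- NULL; av <- numeric()
  molIdx <- 0L; offset <- 0L
  needRelax <- (relax == "always")

  for (p in proteins) {
    ctr <- p@centers
    ctr <- sweep(ctr, 2, colMeans(ctr))  # place by geometric center
    for (cp in seq_len(p@copyNumber)) {
      molIdx <- molIdx + 1L
      placed <- FALSE
      best <- NULL; bestOv <- Inf
      for (att in seq_len(maxAttempts)) {
        R <- .random_rotation()
        shift <- runif(3, 0, boxLength)
        cand <- ctr %*% t(R) + matrix(shift, nrow(ctr), 3, byrow = TRUE)
        ov <- .max_overlap(cand, p@radii, pos, rad, boxLength)
        if (ov <= overlapTol) {
          placed <- TRUE
          best <- cand
          break
        }
        if (ov < bestOv) { bestOv <- ov; best <- cand }
      }
      if (!placed) {
        if (relax == "never")
          stop("placement failure for molecule ", molIdx,
               " after ", maxAttempts,
               " attempts (packing too dense); try relax = 'auto'")
        needRelax <- TRUE
      }
      pos <- rbind(pos, best)
      rad <- c(rad, p@radii)
      molv <- c(molv, rep(molIdx, nrow(ctr)))
      pid <- c(pid, rep(p@proteinId, nrow(ctr)))
      if (nrow(p@bonds) > 0) {
        bonds <- rbind(bonds, p@bonds + offset)
        bl <- c(bl, p@bondLengths)
      }
      if (nrow(p@angles) > 0) {
        angles <- rbind(angles, p@angles + offset)
        av <- c(av, p@angleValues)
      }
      offset <- offset + nrow(ctr)
    }
  }
  if (is.null(bonds)) bonds <- matrix(integer(), 0, 2)
  if (is.null(angles)) angles <- matrix(integer(), 0, 3)

  if (needRelax) {
    res <- cpp_relax(pos, rad, as.integer(molv - 1L), boxLength, 1.0,
                     5000L, overlapTol, 1.0)
    if (!res$converged)
      stop("placement failure: relaxation did not remove overlaps (max overlap ",
           sprintf("%.2f", res$maxOverlap), " A); packing too dense")
    pos <- res$positions
  }
  # wrap molecule-wise (whole-molecule shifts by L) so internal geometry is
  # never split across the boundary
  for (m in unique(molv)) {
    sel <- molv == m
    ctr <- colMeans(pos[sel, , drop = FALSE])
    shift <- -boxLength * floor(ctr / boxLength)
    pos[sel, ] <- sweep(pos[sel, , drop = FALSE], 2, shift, "+")
  }
  new("SystemState", boxLength = boxLength, positions = pos, radii = rad,
      molecule = molv, proteinId = pid, D0 = numeric(),
      frozen = rep(FALSE, length(rad)),
      bonds = matrix(as.integer(bonds), ncol = 2), bondLengths = bl,
      angles = matrix(as.integer(angles), ncol = 3), angleValues = av)
}

# deepest overlap of candidate spheres against placed spheres (min image)
.max_overlap <- function(cand, candR, pos, rad, L) {
  if (is.null(pos) || nrow(pos) == 0) return(0)
  worst <- 0
  for (s in seq_len(nrow(cand))) {
    d <- sweep(pos, 2, cand[s, ])
    d <- d - L * floor(d / L + 0.5)
    dist <- sqrt(rowSums(d^2))
    ov <- (rad + candR[s]) - dist
    m <- max(ov)
    if (m > worst) worst <- m
  }
  worst
}

#' Occupied volume fraction of a box (no-overlap estimate)
#'
#' Sum of sphere volumes over box volume; inter-protein overlaps are excluded
#' by construction, intra-protein overlaps make this a slight overestimate.
#'
#' @param state a \code{\link{SystemState-class}}.
#' @return dimensionless fraction.
#' @export
occupiedFraction <- function(state) {
  sum(4 / 3 * pi * state@radii^3) / state@boxLength^3
}
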
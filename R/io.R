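#' Read C-alpha coordinates from a PDB file
#'
#' Extracts the C-alpha trace (alternate location blank or "A") from the
#' first model of a PDB file.
#'
#' @param path PDB file path.
#' @return numeric matrix (residues x 3), Angstrom.
#' @export
readCalphaPDB <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  sel <- a$elety == "CA" & a$type == "ATOM" &
    (is.na(a$alt) | a$alt %in% c("", "A"))
  if (!any(sel)) stop("no C-alpha atoms found in ", path)
  as.matrix(a[sel, c("x", "y", "z")])
}

#' Read a composition table
#'
#' Tab-separated table with header and columns \code{protein_id},
#' \code{source} (a PDB path, or "synthetic" / "synthetic:<n_spheres>"),
#' \code{molecular_weight} (kDa) and \code{copy_number}. An optional
#' \code{tracer} column (logical) marks tracer species.
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
readCompositionTable <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("protein_id", "source", "molecular_weight", "copy_number")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("composition table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$protein_id)) stop("protein_id values must be unique")
  if (any(tab$copy_number < 1)) stop("copy_number must be >= 1")
  if (!"tracer" %in% names(tab)) tab$tracer <- FALSE
  tab
}

#' Build coarse-grained proteins from a composition table
#'
#' Rows with a PDB path in \code{source} are built by k-means coarse-graining
#' of the structure; rows with source "synthetic" (optionally
#' "synthetic:<n>") get a synthetic sphere cluster with the cluster count
#' implied by the molecular weight (or the stated n).
#'
#' @param composition data.frame from \code{\link{readCompositionTable}}.
#' @param seed base RNG seed; row index is added so entries differ.
#' @param ... passed to \code{\link{buildCGProtein}}.
#' @return list of \code{\link{CGProtein-class}} objects.
#' @export
buildProteins <- function(composition, seed = 1L, ...) {
  lapply(seq_len(nrow(composition)), function(r) {
    row <- composition[r, ]
    if (grepl("^synthetic", row$source)) {
      n <- if (grepl(":", row$source)) {
        as.integer(sub("^synthetic:", "", row$source))
      } else {
        clusterCountForMW(row$molecular_weight)
      }
      p <- makeSyntheticProtein(n, seed = seed + r, proteinId = row$protein_id,
                                copyNumber = row$copy_number,
                                tracer = isTRUE(row$tracer))
      p@molecularWeight <- row$molecular_weight
      p
    } else {
      coords <- readCalphaPDB(row$source)
      buildCGProtein(coords, molecularWeight = row$molecular_weight,
                     proteinId = row$protein_id,
                     copyNumber = row$copy_number,
                     tracer = isTRUE(row$tracer), seed = seed + r, ...)
    }
  })
}

#' Write / read a coarse-grained model as JSON
#'
#' A documented plain-text serialization of one or more
#' \code{\link{CGProtein-class}} objects (centers, radii, topology,
#' equilibrium geometry, metadata).
#'
#' @param proteins a \code{CGProtein} or list of them.
#' @param path output file.
#' @export
writeCGJSON <- function(proteins, path) {
  if (is(proteins, "CGProtein")) proteins <- list(proteins)
  payload <- lapply(proteins, function(p) list(
    protein_id = p@proteinId,
    centers = p@centers,
    radii = p@radii,
    bonds = p@bonds,
    bond_lengths = p@bondLengths,
    angles = p@angles,
    angle_values = p@angleValues,
    molecular_weight = p@molecularWeight,
    copy_number = p@copyNumber,
    tracer = p@tracer
  ))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCGJSON
#' @return \code{readCGJSON}: list of \code{CGProtein} objects.
#' @export
readCGJSON <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  asMat <- function(x, ncol, mode = "double") {
    if (length(x) == 0) return(matrix(vector(mode), 0, ncol))
    m <- do.call(rbind, lapply(x, function(row) unlist(row)))
    storage.mode(m) <- mode
    matrix(m, ncol = ncol)
  }
  lapply(payload, function(p) {
    new("CGProtein", proteinId = p$protein_id,
        centers = asMat(p$centers, 3),
        radii = as.numeric(unlist(p$radii)),
        bonds = asMat(p$bonds, 2, "integer"),
        bondLengths = as.numeric(unlist(p$bond_lengths)),
        angles = asMat(p$angles, 3, "integer"),
        angleValues = as.numeric(unlist(p$angle_values)),
        molecularWeight = as.numeric(p$molecular_weight),
        copyNumber = as.integer(p$copy_number), tracer = isTRUE(p$tracer))
  })
}

#' Write a pseudo-PDB of a coarse-grained model or box
#'
#' One HETATM record per sphere with the sphere radius in the B-factor
#' column, for visualization.
#'
#' @param x a \code{CGProtein} or \code{SystemState}.
#' @param path output file.
#' @export
writePseudoPDB <- function(x, path) {
  if (is(x, "CGProtein")) {
    pos <- x@centers; rad <- x@radii; mol <- rep(1L, nrow(pos))
  } else {
    pos <- wrappedPositions(x); rad <- x@radii; mol <- x@molecule
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(pos))) {
    writeLines(sprintf(
      "HETATM%5d  C   SPH %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      i %% 100000L, LETTERS[(mol[i] - 1L) %% 26L + 1L], mol[i] %% 10000L,
      pos[i, 1], pos[i, 2], pos[i, 3], 1.0, rad[i]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write / read a trajectory as CSV
#'
#' Long-format plain-text trajectory (frame time, sphere index, molecule,
#' unwrapped x/y/z) with a JSON metadata header line (prefixed \code{#}).
#'
#' @param traj a \code{\link{BDTrajectory-class}}.
#' @param path output file.
#' @export
writeTrajectoryCSV <- function(traj, path) {
  d <- dim(traj@frames)
  meta <- list(radii = traj@radii, molecule = traj@molecule,
               proteinId = traj@proteinId, config = traj@config)
  con <- file(path, "w")
  writeLines(paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)), con)
  close(con)
  long <- data.frame(
    time = rep(traj@times, d[2]),
    sphere = rep(seq_len(d[2]), each = d[1]),
    x = as.vector(traj@frames[, , 1]),
    y = as.vector(traj@frames[, , 2]),
    z = as.vector(traj@frames[, , 3])
  )
  suppressWarnings(write.table(long, path, append = TRUE, sep = ",",
                               row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @return \code{readTrajectoryCSV}: a \code{BDTrajectory}.
#' @export
readTrajectoryCSV <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- jsonlite::fromJSON(sub("^#", "", first))
  long <- read.table(path, header = TRUE, sep = ",", comment.char = "#")
  times <- sort(unique(long$time))
  N <- max(long$sphere)
  Tn <- length(times)
  fr <- array(NA_real_, c(Tn, N, 3))
  ord <- order(long$sphere, long$time)
  long <- long[ord, ]
  fr[, , 1] <- matrix(long$x, Tn, N)
  fr[, , 2] <- matrix(long$y, Tn, N)
  fr[, , 3] <- matrix(long$z, Tn, N)
  new("BDTrajectory", times = times, frames = fr,
      molecule = as.integer(meta$molecule),
      proteinId = as.character(meta$proteinId),
      radii = as.numeric(meta$radii),
      config = as.list(meta$config),
      energies = matrix(numeric(), 0, 0), phi = matrix(numeric(), 0, 0))
}

#' Export a trajectory as XYZ for visualization tools
#'
#' @param traj a \code{\link{BDTrajectory-class}}.
#' @param path output file.
#' @param wrap wrap coordinates into the box.
#' @export
writeXYZ <- function(traj, path, wrap = TRUE) {
  d <- dim(traj@frames)
  L <- traj@config$boxLength
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(d[1])) {
    writeLines(as.character(d[2]), con)
    writeLines(sprintf("t=%g ns", traj@times[f]), con)
    xyz <- traj@frames[f, , , drop = TRUE]
    if (d[2] == 1L) xyz <- matrix(xyz, 1, 3)
    if (wrap && !is.null(L)) xyz <- xyz - L * floor(xyz / L)
    writeLines(sprintf("C %.3f %.3f %.3f", xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read / write a simulation configuration as YAML
#'
#' All \code{\link{BDConfig-class}} slots are accepted as top-level keys;
#' missing keys keep their defaults. The full configuration is echoed into
#' every trajectory's metadata.
#'
#' @param path YAML file.
#' @return \code{readBDConfig}: a \code{BDConfig}.
#' @export
readBDConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- slotNames("BDConfig")
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(bdConfig, vals)
}

#' @rdname readBDConfig
#' @param config a \code{BDConfig}.
#' @export
writeBDConfig <- function(config, path) {
  yaml::write_yaml(.config_as_list(config), path)
  invisible(path)
}
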
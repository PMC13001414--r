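#' Write an ensemble as a multi-model PDB file
#'
#' Standard fixed-column ATOM records, one MODEL/ENDMDL block per frame,
#' chain "A", occupancy 1.00, B-factor 0.00, element column populated.
#' Header REMARK 250 lines carry the variant label and the replica id of
#' every model so the file round-trips through [read_ensemble_pdb()].
#'
#' @param ensemble an `ensemble` with coordinates.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (is.null(ensemble$conformations))
    stop("ensemble has no coordinates to write")
  aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
           G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
           M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
           S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK 250 VARIANT %s", ensemble$label), con)
  writeLines(sprintf("REMARK 250 MODEL %d REPLICA %d",
                     seq_along(ensemble$conformations),
                     ensemble$replica), con)
  for (m in seq_along(ensemble$conformations)) {
    cf <- ensemble$conformations[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(cf$xyz)), paste0(" ", cf$atom), aa3[cf$resid], cf$resno,
      cf$xyz[, 1], cf$xyz[, 2], cf$xyz[, 3], 1, 0, cf$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as an ensemble
#'
#' Parsing of ATOM records is delegated to `bio3d::read.pdb`
#' (multi-model mode); REMARK 250 VARIANT/REPLICA header lines written
#' by [write_ensemble_pdb()] are honoured when present, otherwise all
#' models are assigned to a single replica. Truncated ATOM records are
#' rejected with the offending line number before parsing.
#'
#' @param path PDB file path.
#' @return an `ensemble` (sequence, conformations, replica labels; the
#'   dihedral series is recomputed from the coordinates).
#' @export
read_ensemble_pdb <- function(path) {
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (any(is_atom & nchar(lines) < 54)) {
    bad <- which(is_atom & nchar(lines) < 54)[1]
    stop("truncated ATOM record at line ", bad)
  }
  if (!any(grepl("^MODEL", lines)) && !any(is_atom))
    stop("no models / atoms in PDB file")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  aa1 <- bio3d::aa321(pdb$atom$resid)
  resno <- pdb$atom$resno
  seq1 <- paste(aa1[!duplicated(resno)], collapse = "")
  variant <- sub("^REMARK 250 VARIANT +", "",
                 grep("^REMARK 250 VARIANT", lines, value = TRUE))
  label <- if (length(variant)) variant[1] else "ensemble"
  rep_lines <- grep("^REMARK 250 MODEL", lines, value = TRUE)
  replica <- rep(1L, n_models)
  if (length(rep_lines)) {
    mm <- regmatches(rep_lines,
                     regexec("MODEL +([0-9]+) +REPLICA +([0-9]+)", rep_lines))
    for (m in mm) {
      i <- as.integer(m[2])
      if (i >= 1 && i <= n_models) replica[i] <- as.integer(m[3])
    }
  }
  pep <- peptide_sequence(seq1, label)
  confs <- lapply(seq_len(n_models), function(m) {
    structure(list(
      xyz = matrix(xyz[m, ], ncol = 3, byrow = TRUE),
      atom = pdb$atom$elety, resno = resno,
      resid = aa1, element = pdb$atom$elesy,
      sequence = seq1), class = "conformation")
  })
  dih <- compute_dihedrals(structure(
    list(sequence = pep, conformations = confs, replica = replica,
         label = label), class = "ensemble"))
  structure(list(sequence = pep, dihedrals = dih, replica = replica,
                 conformations = confs, label = label),
            class = "ensemble")
}

#' Tidy CSV exports
#'
#' `write_dihedral_csv`: columns `frame, replica, residue_index, phi,
#' psi`. `write_occupancy_csv`: columns `variant, replica, residue,
#' class, fraction`. `write_deviation_csv`: columns `variant, residue,
#' class, delta, uncertainty`. `write_ranking_csv`: the ranking
#' data.frame as-is. All numeric output is written at full precision
#' with no locale-dependent formatting.
#'
#' @param series,occ,dev,ranking the objects to export.
#' @param path output file path.
#' @return `path`, invisibly.
#' @name csv_exports
NULL

#' @rdname csv_exports
#' @export
write_dihedral_csv <- function(series, path) {
  stopifnot(inherits(series, "dihedral_series"))
  n <- nrow(series$phi)
  df <- data.frame(
    frame = rep(seq_len(n), times = length(series$residues)),
    replica = rep(series$replica, times = length(series$residues)),
    residue_index = rep(series$residues, each = n),
    phi = as.vector(series$phi),
    psi = as.vector(series$psi))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname csv_exports
#' @export
write_occupancy_csv <- function(occ, path) {
  stopifnot(inherits(occ, "occupancy_set"))
  arr <- unclass(occ)
  dn <- dimnames(arr)
  df <- expand.grid(residue = dn$residue, class = dn$class,
                    replica = dn$replica, stringsAsFactors = FALSE)
  df$fraction <- as.vector(arr)
  df <- data.frame(variant = attr(occ, "variant"),
                   replica = df$replica, residue = df$residue,
                   class = df$class, fraction = df$fraction)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname csv_exports
#' @export
write_deviation_csv <- function(dev, path) {
  stopifnot(inherits(dev, "deviation_profile"))
  dn <- dimnames(dev$delta)
  df <- expand.grid(residue = dn[[1]], class = dn[[2]],
                    stringsAsFactors = FALSE)
  df$delta <- as.vector(dev$delta)
  df$uncertainty <- as.vector(dev$uncertainty)
  df <- data.frame(variant = dev$variant, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname csv_exports
#' @export
write_ranking_csv <- function(ranking, path) {
  utils::write.csv(as.data.frame(ranking), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a PCA model as JSON
#'
#' @param model an `ssp_pca`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pca_json <- function(model, path) {
  stopifnot(inherits(model, "ssp_pca"))
  jsonlite::write_json(list(
    center = model$center,
    rotation = model$rotation,
    sdev = model$sdev,
    var_explained = model$var_explained
  ), path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' HILLS-style text I/O for bias traces
#'
#' Whitespace-delimited columns `time center width height biasf`, one
#' row per deposited hill, in the spirit of common metadynamics
#' post-processors.
#'
#' @param trace a `hill_trace`.
#' @param path file path.
#' @return `write_hills`: `path` invisibly; `read_hills`: a
#'   `hill_trace`.
#' @export
write_hills <- function(trace, path) {
  stopifnot(inherits(trace, "hill_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#! FIELDS time center width height biasf"), con)
  writeLines(sprintf("#! SET temperature %.6g", trace$temperature), con)
  writeLines(sprintf("#! SET nominal_height %.6g", trace$height), con)
  h <- trace$hills
  writeLines(sprintf("%.6f %.10g %.10g %.10g %.6g",
                     h$time, h$center, h$width, h$height, trace$gamma),
             con)
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  lines <- readLines(path)
  temp <- as.numeric(sub(".*temperature ", "",
                         grep("SET temperature", lines, value = TRUE)[1]))
  h0 <- as.numeric(sub(".*nominal_height ", "",
                       grep("SET nominal_height", lines, value = TRUE)[1]))
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "[[:space:]]+"),
                             as.numeric))
  trace <- wtm_trace(height = h0, width = m[1, 3], gamma = m[1, 5],
                     temperature = temp)
  trace$hills <- data.frame(time = m[, 1], center = m[, 2],
                            width = m[, 3], height = m[, 4])
  trace
}

#' Region map config I/O (YAML)
#'
#' A region map is stored as `region -> list of rectangles`, each
#' rectangle a list with `phi_lo, phi_hi, psi_lo, psi_hi`.
#'
#' @param map a `region_map`.
#' @param path file path.
#' @return `write_region_map`: `path` invisibly; `read_region_map`: a
#'   validated `region_map`.
#' @export
write_region_map <- function(map, path) {
  obj <- lapply(map, function(r)
    lapply(seq_len(nrow(r)), function(j) as.list(r[j, ])))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_region_map
#' @export
read_region_map <- function(path) {
  obj <- yaml::read_yaml(path)
  known <- setdiff(RAMA_CLASSES, "unassigned")
  bad <- setdiff(names(obj), known)
  if (length(bad))
    stop("unknown region name(s) in config: ", paste(bad, collapse = ", "))
  map <- structure(lapply(obj, function(rects)
    do.call(rbind, lapply(rects, as.data.frame))), class = "region_map")
  validate_region_map(map)
  map
}
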
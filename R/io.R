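# Structure and trajectory I/O. GRO is the canonical format (nm, fixed
# width, 0.001 nm precision); PDB and DCD are read through bio3d. Residue
# names map to site roles through a documented table; atom names encode the
# role details so a written frame reads back with full labels.
#
# Residue-name mapping: SOL/HOH/WAT -> water; CAL -> callose;
# CEL -> cellulose; GLC -> callose (generic glucan). Anything else is
# reported and aborts the read unless permissive = TRUE (unmapped residues
# are then dropped).
#
# Atom-name scheme: OW/HW* water; C* ring carbons; OR ring oxygen; OG
# glycosidic oxygen; O<digit> hydroxyl oxygen at that carbon; OT terminal
# hydroxyl; all other H* are polymer hydrogens.

.res_map <- c(SOL = "water", HOH = "water", WAT = "water",
              CAL = "callose", CEL = "cellulose", GLC = "callose")

.atom_name <- function(labels) {
  n <- nrow(labels)
  out <- character(n)
  wO <- labels$role == "water_O"; wH <- labels$role == "water_H"
  out[wO] <- "OW"
  # number water hydrogens 1,2 within each molecule
  hw <- which(wH)
  if (length(hw)) out[hw] <- paste0("HW", rep_len(1:2, length(hw)))
  out[labels$role == "poly_C"] <- "C"
  out[labels$role == "poly_ring_O"] <- "OR"
  out[labels$role == "poly_glycosidic_O"] <- "OG"
  hy <- labels$role == "poly_hydroxyl_O"
  out[hy & !is.na(labels$attach)] <- paste0("O", labels$attach[hy & !is.na(labels$attach)])
  out[hy & is.na(labels$attach)] <- "OT"
  out[labels$role == "poly_H"] <- "H"
  # disambiguate repeated C/H names within a residue by numbering
  out
}

.infer_labels <- function(resname, atomname, permissive) {
  phase <- unname(.res_map[resname])
  unknown <- is.na(phase)
  report <- data.frame(residue = unique(resname[unknown]))
  if (any(unknown) && !permissive)
    stop("unmapped residue name(s): ", paste(report$residue, collapse = ", "),
         "; rerun with permissive = TRUE to drop them")
  keep <- !unknown
  resname <- resname[keep]; atomname <- atomname[keep]
  phase <- phase[keep]
  first <- toupper(substr(atomname, 1L, 1L))
  water <- phase == "water"
  role <- character(length(atomname))
  attach <- rep(NA_integer_, length(atomname))
  role[water & first == "O"] <- "water_O"
  role[water & first == "H"] <- "water_H"
  poly <- !water
  an <- toupper(atomname)
  role[poly & first == "C"] <- "poly_C"
  role[poly & first == "H"] <- "poly_H"
  po <- poly & first == "O"
  role[po & substr(an, 2L, 2L) == "R"] <- "poly_ring_O"
  role[po & substr(an, 2L, 2L) == "G"] <- "poly_glycosidic_O"
  role[po & substr(an, 2L, 2L) == "T"] <- "poly_hydroxyl_O"
  dig <- po & substr(an, 2L, 2L) %in% c("2", "3", "4", "6")
  role[dig] <- "poly_hydroxyl_O"
  attach[dig] <- as.integer(substr(an[dig], 2L, 2L))
  if (any(role == ""))
    stop("cannot infer a role for atom name(s): ",
         paste(unique(atomname[role == ""]), collapse = ", "))
  if (!all(first %in% c("O", "H", "C")))
    stop("unsupported element in atom name(s): ",
         paste(unique(atomname[!first %in% c("O", "H", "C")]), collapse = ", "))
  element <- first
  polymer <- ifelse(water, "none", phase)
  list(element = element, role = role, polymer = polymer, attach = attach,
       keep = keep, report = report)
}

# chain/ring assignment from the residue-id sequence of polymer atoms: ring
# index = residue id; a new chain starts whenever the residue id fails to
# increase (each chain numbers its rings from 1 upward).
.infer_chains <- function(resid, is_poly) {
  chain <- rep(NA_integer_, length(resid))
  ring <- rep(NA_integer_, length(resid))
  idx <- which(is_poly)
  if (!length(idx)) return(list(chain = chain, ring = ring))
  rid <- resid[idx]
  newres <- c(TRUE, rid[-1L] != rid[-length(rid)])
  resseq <- rid[newres]
  chain_of_res <- cumsum(c(TRUE, diff(resseq) <= 0))
  chain[idx] <- chain_of_res[cumsum(newres)]
  ring[idx] <- rid
  list(chain = chain, ring = ring)
}

parse_gro_frame <- function(lines, start, path) {
  title <- lines[start]
  natoms <- suppressWarnings(as.integer(trimws(lines[start + 1L])))
  if (is.na(natoms))
    stop("malformed atom count at line ", start + 1L, " of ", path)
  if (start + 1L + natoms + 1L > length(lines))
    stop("truncated GRO frame starting at line ", start, " of ", path)
  al <- lines[start + 1L + seq_len(natoms)]
  resid <- suppressWarnings(as.integer(substr(al, 1L, 5L)))
  resname <- trimws(substr(al, 6L, 10L))
  atomname <- trimws(substr(al, 11L, 15L))
  x <- suppressWarnings(as.numeric(substr(al, 21L, 28L)))
  y <- suppressWarnings(as.numeric(substr(al, 29L, 36L)))
  z <- suppressWarnings(as.numeric(substr(al, 37L, 44L)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed atom line ", start + 1L + bad[1L], " of ", path)
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(
    lines[start + 2L + natoms]), "\\s+")[[1L]]))
  if (length(boxv) == 9L) {
    if (any(abs(boxv[4:9]) > 1e-9))
      stop("triclinic box in ", path, "; only orthorhombic boxes are supported")
    boxv <- boxv[1:3]
  }
  if (length(boxv) != 3L || any(is.na(boxv)) || any(boxv <= 0))
    stop("malformed box line ", start + 2L + natoms, " of ", path)
  time <- NA_real_
  tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  if (length(tm)) time <- as.numeric(sub("t=\\s*", "", tm))
  list(natoms = natoms, resid = resid, resname = resname,
       atomname = atomname, coords = cbind(x, y, z), box = boxv,
       time = time, next_start = start + natoms + 3L)
}

#' Read a single-frame structure file
#'
#' Parses a GRO (nm) or PDB (Angstrom, converted) file into a single-frame
#' labeled trajectory, inferring site labels from residue and atom names.
#' Unmapped residue names abort the read unless `permissive = TRUE` (they
#' are then dropped); either way they are listed in the
#' `inference_report` attribute.
#'
#' @param path file path.
#' @param format `"gro"` or `"pdb"` (default: from the file extension).
#' @param permissive drop unmapped residues instead of failing.
#' @return a single-frame [labeled_trajectory()] with attribute
#'   `inference_report`.
#' @export
read_structure <- function(path, format = NULL, permissive = FALSE) {
  if (is.null(format))
    format <- tolower(sub(".*\\.", "", path))
  format <- match.arg(format, c("gro", "pdb"))
  if (format == "gro") {
    lines <- readLines(path)
    fr <- parse_gro_frame(lines, 1L, path)
    resid <- fr$resid; resname <- fr$resname; atomname <- fr$atomname
    coords <- fr$coords; box <- fr$box
    time <- if (is.na(fr$time)) 0 else fr$time
  } else {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    a <- pdb$atom
    resid <- as.integer(a$resno); resname <- a$resid; atomname <- a$elety
    coords <- cbind(a$x, a$y, a$z) / 10
    cl <- grep("^CRYST1", readLines(path), value = TRUE)
    if (!length(cl))
      stop("PDB file ", path, " has no CRYST1 record; box unknown")
    abc <- as.numeric(c(substr(cl[1L], 7, 15), substr(cl[1L], 16, 24),
                        substr(cl[1L], 25, 33)))
    ang <- as.numeric(c(substr(cl[1L], 34, 40), substr(cl[1L], 41, 47),
                        substr(cl[1L], 48, 54)))
    if (any(is.na(abc)) || any(abc <= 0))
      stop("malformed CRYST1 record in ", path)
    if (any(!is.na(ang) & abs(ang - 90) > 1e-6))
      stop("non-orthorhombic CRYST1 in ", path)
    box <- abc / 10
    time <- 0
  }
  inf <- .infer_labels(resname, atomname, permissive)
  resid <- resid[inf$keep]; coords <- coords[inf$keep, , drop = FALSE]
  ch <- .infer_chains(resid, inf$polymer != "none")
  labels <- site_labels(inf$element, inf$role, polymer = inf$polymer,
                        chain = ch$chain, ring = ch$ring, attach = inf$attach)
  out <- labeled_trajectory(coords, box = box, labels = labels, time = time)
  attr(out, "inference_report") <- inf$report
  out
}

#' Read a multi-frame trajectory
#'
#' `"multi_gro"` reads concatenated GRO frames (frame times from `t=` in
#' the title lines when present); `"dcd"` reads a binary DCD through
#' bio3d, taking labels from a GRO topology file. XTC is not supported;
#' convert to DCD or multi-GRO first.
#'
#' @param topology GRO file providing the labels (for DCD; ignored for
#'   multi-GRO, whose first frame carries them).
#' @param path trajectory file.
#' @param format `"multi_gro"` or `"dcd"`.
#' @param stride keep every `stride`-th frame.
#' @param permissive passed to the label inference.
#' @return a [labeled_trajectory()].
#' @export
read_trajectory <- function(path, topology = NULL,
                            format = c("multi_gro", "dcd", "xtc"),
                            stride = 1L, permissive = FALSE) {
  format <- match.arg(format)
  if (format == "xtc")
    stop("XTC reading is not supported; convert to DCD or multi-GRO")
  if (format == "multi_gro") {
    lines <- readLines(path)
    frames <- list(); start <- 1L; ref <- NULL
    while (start <= length(lines) && nzchar(trimws(lines[start]))) {
      fr <- parse_gro_frame(lines, start, path)
      if (is.null(ref)) ref <- fr
      else if (fr$natoms != ref$natoms)
        stop("frame ", length(frames) + 1L, " has ", fr$natoms,
             " atoms; expected ", ref$natoms, " (last good frame: ",
             length(frames), ")")
      frames[[length(frames) + 1L]] <- fr
      start <- fr$next_start
    }
    if (!length(frames)) stop("no frames in ", path)
    keep <- seq(1L, length(frames), by = stride)
    frames <- frames[keep]
    inf <- .infer_labels(ref$resname, ref$atomname, permissive)
    ch <- .infer_chains(ref$resid[inf$keep], inf$polymer != "none")
    labels <- site_labels(inf$element, inf$role, polymer = inf$polymer,
                          chain = ch$chain, ring = ch$ring, attach = inf$attach)
    times <- vapply(frames, `[[`, numeric(1L), "time")
    if (any(is.na(times))) times <- (keep - 1L)
    out <- labeled_trajectory(lapply(frames, function(f)
      f$coords[inf$keep, , drop = FALSE]),
      box = do.call(rbind, lapply(frames, `[[`, "box")),
      labels = labels, time = times)
    attr(out, "inference_report") <- inf$report
    return(out)
  }
  # DCD
  if (is.null(topology)) stop("DCD reading requires a GRO topology")
  top <- read_structure(topology, format = "gro", permissive = permissive)
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  cell <- bio3d::read.dcd(path, cell = TRUE, verbose = FALSE)
  nat <- ncol(xyz) / 3L
  if (nat != n_sites(top))
    stop("DCD atom count ", nat, " does not match topology (", n_sites(top), ")")
  if (any(abs(cell[, 4:6] - 90) > 1e-6))
    stop("non-orthorhombic cell in ", path)
  keep <- seq(1L, nrow(xyz), by = stride)
  boxes <- cell[keep, 1:3, drop = FALSE] / 10
  coords <- lapply(keep, function(f)
    matrix(xyz[f, ], ncol = 3L, byrow = TRUE) / 10)  # bio3d xyz is x1,y1,z1,...
  labeled_trajectory(coords, box = boxes, labels = top$labels,
                     time = seq_along(keep) - 1)
}

#' Write a trajectory to a GRO file
#'
#' Writes one GRO block per frame (multi-GRO). Polymer atoms are grouped by
#' chain and residue so the chain structure is recoverable on reading;
#' water molecules follow. Coordinates are written at the format's 0.001 nm
#' precision.
#'
#' @param traj a `labeled_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path) {
  lab <- traj$labels
  poly <- which(lab$polymer != "none")
  wat <- which(lab$polymer == "none")
  ord <- c(poly[order(lab$chain[poly], lab$ring[poly])], wat)
  names_out <- .atom_name(lab)[ord]
  resname <- ifelse(lab$polymer[ord] == "callose", "CAL",
             ifelse(lab$polymer[ord] == "cellulose", "CEL", "SOL"))
  resid <- integer(length(ord))
  np <- sum(lab$polymer[ord] != "none")
  if (np) resid[seq_len(np)] <- lab$ring[ord[seq_len(np)]]
  if (length(ord) > np) {
    wo <- lab$role[ord] == "water_O"
    resid[(np + 1L):length(ord)] <- cumsum(wo)[(np + 1L):length(ord)]
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    x <- traj$coords[[f]][ord, , drop = FALSE]
    writeLines(sprintf("glucan hydrogel frame, t= %g", traj$time[f]), con)
    writeLines(sprintf("%5d", length(ord)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       resid %% 100000L, resname, names_out,
                       seq_along(ord) %% 100000L,
                       x[, 1L], x[, 2L], x[, 3L]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[f, 1L],
                       traj$box[f, 2L], traj$box[f, 3L]), con)
  }
  invisible(path)
}

#' Read a key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; values that parse
#' as numbers are returned numeric, comma-separated values as vectors.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    vals <- trimws(strsplit(kv[2L], ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (all(!is.na(num))) num else vals
  }
  out
}
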
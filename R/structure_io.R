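#' Read alpha carbons from a PDB or mmCIF structure file
#'
#' Parses a structure file, keeps alpha-carbon (CA) atoms of the twenty
#' standard amino acids, resolves alternate locations deterministically
#' (altloc blank or 'A' preferred, then highest occupancy), and optionally
#' expands a biological assembly (PDB `REMARK 350` transforms; chains of the
#' n-th copy are suffixed `.n`).  Residue numbering is taken from the file's
#' author numbers; numbering gaps are preserved, since residue distances are
#' defined on the numbers themselves.
#'
#' @param path path to the structure file.
#' @param format `"pdb"`, `"cif"`, or `"auto"` (from the file extension).
#' @param assembly optional integer: expand the numbered biological assembly
#'   (PDB input only).
#' @param residue_range optional inclusive `c(first, last)` author residue
#'   numbers to keep.
#' @param chain_ids optional chains to keep (applied before assembly
#'   expansion).
#' @return an [alpha_carbon_cloud()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           assembly = NULL, residue_range = NULL,
                           chain_ids = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "pdb") bio3d::read.pdb(path) else bio3d::read.cif(path)),
    error = function(e) stop("could not parse ", format, " file '", path,
                             "': ", conditionMessage(e)))
  atoms <- parsed$atom
  keep <- atoms$type == "ATOM" & atoms$elety == "CA" &
    atoms$resid %in% .standard_aa
  atoms <- atoms[keep, , drop = FALSE]
  atoms <- .resolve_altloc(atoms)
  df <- data.frame(chain = as.character(atoms$chain),
                   residue = as.integer(atoms$resno),
                   x = atoms$x, y = atoms$y, z = atoms$z,
                   stringsAsFactors = FALSE)
  if (!is.null(chain_ids)) df <- df[df$chain %in% chain_ids, , drop = FALSE]
  if (!is.null(residue_range)) {
    df <- df[df$residue >= residue_range[1] & df$residue <= residue_range[2], ,
             drop = FALSE]
  }
  if (nrow(df) == 0L) stop("empty selection: no alpha carbons match")
  if (!is.null(assembly)) {
    if (format != "pdb") {
      stop("assembly expansion is only supported for PDB input")
    }
    df <- .expand_assembly(df, path, assembly)
  }
  alpha_carbon_cloud(df, residue_range = residue_range)
}

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

# one CA per (chain, residue): altloc '' or 'A' first, then highest occupancy,
# never silently dropping whole chains
.resolve_altloc <- function(atoms) {
  if (nrow(atoms) == 0L) return(atoms)
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  pref <- ifelse(alt %in% c("", "A"), 0L, 1L)
  ord <- order(pref, -occ, alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(atoms[c("chain", "resno")]), , drop = FALSE]
}

# REMARK 350 BIOMT expansion for one numbered biomolecule
.expand_assembly <- function(df, path, assembly) {
  lines <- readLines(path, warn = FALSE)
  r350 <- lines[startsWith(lines, "REMARK 350")]
  if (length(r350) == 0L) stop("no REMARK 350 assembly information in file")
  biomol <- cumsum(grepl("BIOMOLECULE:", r350))
  block <- r350[biomol == assembly]
  if (length(block) == 0L) stop("assembly ", assembly, " not present")
  chain_lines <- grep("APPLY THE FOLLOWING TO CHAINS:|AND CHAINS:", block,
                      value = TRUE)
  chains <- unlist(lapply(chain_lines, function(l) {
    spec <- sub(".*CHAINS:", "", l)
    trimws(strsplit(spec, ",")[[1]])
  }))
  chains <- chains[nzchar(chains)]
  biomt <- grep("^REMARK 350   BIOMT", block, value = TRUE)
  if (length(biomt) %% 3 != 0 || length(biomt) == 0L) {
    stop("malformed BIOMT records for assembly ", assembly)
  }
  n_ops <- length(biomt) / 3
  sub_df <- df[df$chain %in% chains, , drop = FALSE]
  if (nrow(sub_df) == 0L) stop("assembly chains absent from selection")
  out <- vector("list", n_ops)
  for (op in seq_len(n_ops)) {
    rows <- biomt[(op - 1) * 3 + 1:3]
    mat <- unname(t(vapply(rows, function(l) {
      as.numeric(strsplit(trimws(substring(l, 24)), "\\s+")[[1]])
    }, numeric(4))))
    rot <- mat[, 1:3]
    trans <- mat[, 4]
    xyz <- as.matrix(sub_df[c("x", "y", "z")]) %*% t(rot)
    xyz <- sweep(xyz, 2, trans, "+")
    copy <- sub_df
    copy$x <- xyz[, 1]
    copy$y <- xyz[, 2]
    copy$z <- xyz[, 3]
    identity_op <- isTRUE(all.equal(rot, diag(3), tolerance = 1e-8)) &&
      isTRUE(all.equal(trans, c(0, 0, 0), tolerance = 1e-8))
    if (!identity_op || op > 1) {
      copy$chain <- paste0(copy$chain, ".", op)
    }
    out[[op]] <- copy
  }
  do.call(rbind, out)
}

#' Read a trajectory into a frame set
#'
#' Accepts either the package's per-frame CSV alpha-carbon table (columns
#' `frame, chain, residue, x, y, z`) or a multi-model PDB file, where each
#' `MODEL` is one frame (frames numbered from 0).  Frames with index below
#' `start_frame` are discarded, which drops the early equilibration part of a
#' molecular-dynamics trajectory.
#'
#' @param path trajectory file.
#' @param label `"glycosylated"`, `"aglycosylated"`, or `"unlabeled"`.
#' @param trajectory_id integer identifier.
#' @param start_frame first frame index to retain.
#' @param format `"csv"`, `"pdb"`, or `"auto"`.
#' @return a [trajectory_frames()] object.
#' @export
read_frames <- function(path, label = "unlabeled", trajectory_id = 0L,
                        start_frame = 0L, format = c("auto", "csv", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(csv|tsv|txt)$", path, ignore.case = TRUE))
      "csv" else "pdb"
  }
  if (format == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    required <- c("frame", "chain", "residue", "x", "y", "z")
    if (!all(required %in% names(tab))) {
      stop("trajectory table must have columns frame, chain, residue, x, y, z")
    }
    idx <- sort(unique(tab$frame))
    clouds <- lapply(idx, function(f) {
      alpha_carbon_cloud(tab[tab$frame == f,
                             c("chain", "residue", "x", "y", "z")])
    })
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    keep <- pdb$atom$type == "ATOM" & pdb$atom$elety == "CA" &
      pdb$atom$resid %in% .standard_aa
    at <- pdb$atom[keep, , drop = FALSE]
    sel_xyz <- .atom2xyz(which(keep))
    nm <- nrow(pdb$xyz)
    idx <- seq_len(nm) - 1L
    clouds <- lapply(seq_len(nm), function(m) {
      co <- matrix(pdb$xyz[m, sel_xyz], ncol = 3, byrow = TRUE)
      alpha_carbon_cloud(data.frame(chain = as.character(at$chain),
                                    residue = as.integer(at$resno),
                                    x = co[, 1], y = co[, 2], z = co[, 3],
                                    stringsAsFactors = FALSE))
    })
  }
  keep <- idx >= start_frame
  if (!any(keep)) stop("start_frame excludes every frame")
  trajectory_frames(clouds[keep], label = label,
                    trajectory_id = trajectory_id,
                    frame_indices = idx[keep])
}

# indices of xyz coordinate triplets for atom rows
.atom2xyz <- function(i) as.vector(t(cbind(3 * i - 2, 3 * i - 1, 3 * i)))

#' Write clouds or frame sets to the package's CSV alpha-carbon table
#'
#' The table has columns `frame, chain, residue, x, y, z` (angstroms) and is
#' the package's exchange format, so externally produced molecular-dynamics
#' output can be converted once and then flow through the same readers as
#' everything else.  A single cloud is written as frame 0.
#'
#' @param x an [alpha_carbon_cloud()] or [trajectory_frames()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cloud_table <- function(x, path) {
  if (inherits(x, "alpha_carbon_cloud")) {
    frames <- list(x)
    idx <- 0L
  } else if (inherits(x, "trajectory_frames")) {
    frames <- x$frames
    idx <- x$frame_indices
  } else {
    stop("x must be an alpha_carbon_cloud or trajectory_frames object")
  }
  tabs <- Map(function(cl, f) {
    cbind(frame = f, as.data.frame(cl))
  }, frames, idx)
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a single cloud from a CSV alpha-carbon table
#'
#' @param path table written by [write_cloud_table()].
#' @param frame which frame to extract (default: the first present).
#' @inheritParams read_structure
#' @return an [alpha_carbon_cloud()].
#' @export
read_cloud_table <- function(path, frame = NULL, residue_range = NULL,
                             chain_ids = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(frame)) frame <- min(tab$frame)
  tab <- tab[tab$frame == frame, , drop = FALSE]
  if (nrow(tab) == 0L) stop("frame ", frame, " not present in table")
  cloud <- alpha_carbon_cloud(tab[c("chain", "residue", "x", "y", "z")])
  if (!is.null(residue_range) || !is.null(chain_ids)) {
    cloud <- restrict_cloud(cloud, residue_range, chain_ids)
  }
  cloud
}
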
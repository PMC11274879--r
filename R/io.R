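# Trajectory and report I/O: multi-model PDB, a plain-text columnar frame
# store with JSON sidecar, and run manifests.

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

.chain_ids <- c(LETTERS, letters, 0:9)

#' Write trajectory frames to disk
#'
#' `format = "pdb"` writes a multi-model PDB with one MODEL per frame, one
#' chain per peptide and the bead pseudo-atom names (N, CA, C, CB);
#' coordinates are in Angstrom at PDB precision (3 decimals).
#' `format = "columnar"` writes a full-precision CSV (one row per bead and
#' frame) plus a JSON sidecar with box size, times and provenance; this
#' round-trips bit-exactly through [read_frames()].
#'
#' @param traj A `dmd_trajectory`.
#' @param path Output file (`.pdb`, or `.csv` whose sidecar is
#'   `<path>.json`).
#' @param format `"pdb"` or `"columnar"`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(traj, path, format = c("pdb", "columnar")) {
  format <- match.arg(format)
  b <- traj$beads
  if (format == "pdb") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("REMARK   generated by abetadmd %s",
                       as.character(utils::packageVersion("abetadmd"))), con)
    for (f in seq_along(traj$times)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      pos <- traj$frames[, , f]
      # columns: serial 7-11, name 13-16, altLoc 17 (blank), resName
      # 18-20, chainID 22, resSeq 23-26, x/y/z 31-54
      lines <- sprintf(
        "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        seq_len(nrow(b)),
        ifelse(b$role == "CA", " CA ", paste0(" ", formatC(b$role, width = -3))),
        .aa3[b$aa], .chain_ids[(b$peptide - 1L) %% length(.chain_ids) + 1L],
        b$residue, pos[, 1L], pos[, 2L], pos[, 3L])
      writeLines(lines, con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    nb <- nrow(b)
    nf <- length(traj$times)
    df <- data.frame(
      frame = rep(seq_len(nf), each = nb),
      peptide = rep(b$peptide, nf),
      residue = rep(b$residue, nf),
      role = rep(b$role, nf),
      aa = rep(b$aa, nf),
      x = sprintf("%.17g", as.vector(traj$frames[, 1L, ])),
      y = sprintf("%.17g", as.vector(traj$frames[, 2L, ])),
      z = sprintf("%.17g", as.vector(traj$frames[, 3L, ])))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    sidecar <- list(box = traj$box, times = sprintf("%.17g", traj$times),
                    n_beads = nb, n_frames = nf,
                    seed = traj$seed,
                    engine_version = traj$engine_version,
                    isoform = if (!is.null(traj$topologies))
                      traj$topologies[[1L]]$spec$isoform_id else NULL)
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a columnar frame store
#'
#' Rebuilds the analysis-facing subset of a trajectory (frames, times,
#' beads, box) from the CSV + JSON sidecar written by
#' [write_frames(format = "columnar")]; coordinates round-trip bit-exactly.
#'
#' @param path The CSV path.
#' @return A `dmd_trajectory` (analysis subset; no engine state).
#' @export
read_frames <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, colClasses = c(
    frame = "integer", peptide = "integer", residue = "integer",
    role = "character", aa = "character",
    x = "character", y = "character", z = "character"))
  nb <- side$n_beads; nf <- side$n_frames
  frames <- array(NA_real_, c(nb, 3L, nf))
  frames[, 1L, ] <- as.double(df$x)
  frames[, 2L, ] <- as.double(df$y)
  frames[, 3L, ] <- as.double(df$z)
  b1 <- df[df$frame == 1L, c("peptide", "residue", "role", "aa")]
  rownames(b1) <- NULL
  topo <- NULL
  if (!is.null(side$isoform) &&
      side$isoform %in% c("Ab38", "Ab40", "Ab42", "Ab43")) {
    tp <- build_topology(build_sequence(side$isoform))
    topo <- rep(list(tp), length(unique(b1$peptide)))
  }
  structure(list(
    frames = frames, times = as.double(side$times), beads = b1,
    box = as.double(side$box), topologies = topo, seed = side$seed,
    engine_version = side$engine_version
  ), class = "dmd_trajectory")
}

# small deterministic polynomial hash for manifests (hex string); kept in
# exact double-precision integer range
.config_fingerprint <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Write a run manifest
#'
#' Records the configuration (and its hash), seeds, engine version,
#' per-stage output paths and a timestamp, so every artifact on disk is
#' reachable from exactly one manifest and any figure-style output is
#' reproducible from manifest plus seed.
#'
#' @param config A `simulation_config`.
#' @param outputs Named list of output paths.
#' @param path Manifest path (JSON).
#' @param seeds Integer vector of replica seeds.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, outputs, path, seeds = config$seed) {
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  manifest <- list(
    config = unclass(config),
    config_hash = .config_fingerprint(as.character(cfg_json)),
    seeds = seeds,
    engine_version = as.character(utils::packageVersion("abetadmd")),
    outputs = outputs,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Export a contact map as TSV
#'
#' Square matrix with residue indices as row and column names.
#'
#' @param cm A `contact_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(cm, path) {
  m <- cm$map
  dimnames(m) <- list(seq_len(nrow(m)), seq_len(ncol(m)))
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
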
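# Abeta isoform sequences, hydropathy classes, and four-bead chain topology.

# The 43-residue Abeta1-43 primary structure; the shorter physiological
# isoforms are its N-terminal prefixes.
.ab43_sequence <- "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIAT"

.isoform_lengths <- c(Ab38 = 38L, Ab40 = 40L, Ab42 = 42L, Ab43 = 43L)

# Named regions, 1-based inclusive on the Abeta1-43 numbering:
# central hydrophobic cluster, central folding region, midhydrophobic
# region, C-terminal region.
.ab_regions <- list(CHC = c(17L, 21L), CFR = c(21L, 30L),
                    MHR = c(31L, 36L), CTR = c(39L, 43L))

#' Build a peptide specification
#'
#' Returns the sequence, length and named region annotations for one of the
#' four amyloid-beta isoforms (`"Ab38"`, `"Ab40"`, `"Ab42"`, `"Ab43"`), or
#' for a custom one-letter sequence.  Regions (CHC 17-21, CFR 21-30,
#' MHR 31-36, CTR 39-43) are clipped to the sequence length and dropped when
#' they fall entirely outside it.
#'
#' @param isoform_id One of `"Ab38"`, `"Ab40"`, `"Ab42"`, `"Ab43"`, or an
#'   arbitrary one-letter amino-acid sequence (treated as a custom peptide).
#' @return An object of class `peptide_spec`: a list with elements
#'   `isoform_id`, `sequence`, `length`, and `regions` (named list of
#'   `c(start, end)` integer pairs, 1-based inclusive).
#' @examples
#' build_sequence("Ab42")$length   # 42
#' @export
build_sequence <- function(isoform_id) {
  stopifnot(is.character(isoform_id), length(isoform_id) == 1L)
  if (isoform_id %in% names(.isoform_lengths)) {
    len <- .isoform_lengths[[isoform_id]]
    seq <- substr(.ab43_sequence, 1L, len)
    id <- isoform_id
  } else {
    seq <- toupper(isoform_id)
    letters1 <- strsplit(seq, "", fixed = TRUE)[[1L]]
    if (length(letters1) == 0L) {
      stop("empty sequence")
    }
    bad <- setdiff(letters1, aa_alphabet())
    if (length(bad) > 0L) {
      stop("unknown isoform id or illegal residue letter(s): ",
           paste(unique(bad), collapse = ", "))
    }
    len <- length(letters1)
    id <- "custom"
  }
  regions <- lapply(.ab_regions, function(r) {
    if (r[1L] > len) return(NULL)
    c(r[1L], min(r[2L], len))
  })
  regions <- regions[!vapply(regions, is.null, logical(1L))]
  structure(
    list(isoform_id = id, sequence = seq, length = len, regions = regions),
    class = "peptide_spec"
  )
}

#' @export
print.peptide_spec <- function(x, ...) {
  cat(sprintf("<peptide_spec> %s, %d residues\n", x$isoform_id, x$length))
  cat(" ", x$sequence, "\n")
  for (nm in names(x$regions)) {
    r <- x$regions[[nm]]
    cat(sprintf("  %s: %d-%d\n", nm, r[1L], r[2L]))
  }
  invisible(x)
}

#' Classify a residue by hydropathy
#'
#' Ile, Phe, Cys, Val, Ala and Met are hydrophobic; His, Gln and Asn are
#' uncharged hydrophilic; Arg, Lys, Asp and Glu are charged hydrophilic; the
#' remaining residues (low hydropathy magnitude) are neutral and feel no
#' residue-specific hydropathic potential.
#'
#' @param residue One-letter amino-acid code(s); vectorised.
#' @return Character vector with values in `"hydrophobic"`,
#'   `"uncharged_hydrophilic"`, `"charged_hydrophilic"`, `"neutral"`.
#' @examples
#' classify_hydropathy("I")  # "hydrophobic"
#' @export
classify_hydropathy <- function(residue) {
  residue <- toupper(residue)
  bad <- setdiff(residue, aa_alphabet())
  if (length(bad) > 0L) {
    stop("invalid amino-acid letter(s): ", paste(unique(bad), collapse = ", "))
  }
  out <- rep("neutral", length(residue))
  out[residue %in% c("I", "F", "C", "V", "A", "M")] <- "hydrophobic"
  out[residue %in% c("H", "Q", "N")] <- "uncharged_hydrophilic"
  out[residue %in% c("R", "K", "D", "E")] <- "charged_hydrophilic"
  out
}

#' Build the four-bead chain topology for a peptide
#'
#' Each residue contributes an amide N, an alpha-carbon CA, a carbonyl C and
#' (except glycine) a side-chain CB bead.  Bonded square-well constraints
#' cover the covalent links (N-CA, CA-C, C-N(next), CA-CB) at canonical
#' backbone lengths with +/-2% widths, plus next-neighbour pseudo-bonds
#' (N-C, CA-N(next), C-CA(next), N-CB, C-CB) at ideal-geometry distances
#' with +/-2.5% widths.  The pseudo-bonds fix the bond angles while leaving
#' the phi/psi-like backbone dihedrals free.
#'
#' @param spec A `peptide_spec` from [build_sequence()].
#' @return An object of class `bead_topology`: a list with `spec`, `beads`
#'   (data frame: `idx`, `residue`, `role`, `aa`, `mass`, `hydropathy`) and
#'   `bonds` (data frame: `i`, `j`, `dmin`, `dmax`, `kind`).  Distances in
#'   Angstrom, 1-based bead indices.
#' @examples
#' topo <- build_topology(build_sequence("Ab42"))
#' nrow(topo$beads)  # 162 = 4*42 - 6 glycines
#' @export
build_topology <- function(spec) {
  stopifnot(inherits(spec, "peptide_spec"))
  aa <- strsplit(spec$sequence, "", fixed = TRUE)[[1L]]
  L <- length(aa)
  if (L == 0L) stop("empty sequence")
  cc <- ff_constants()

  res_idx <- integer(0); role <- character(0); res_aa <- character(0)
  for (i in seq_len(L)) {
    roles <- if (aa[i] == "G") c("N", "CA", "C") else c("N", "CA", "C", "CB")
    res_idx <- c(res_idx, rep(i, length(roles)))
    role <- c(role, roles)
    res_aa <- c(res_aa, rep(aa[i], length(roles)))
  }
  n_beads <- length(role)
  beads <- data.frame(
    idx = seq_len(n_beads), residue = res_idx, role = role, aa = res_aa,
    mass = rep(cc$bead_mass, n_beads),
    hydropathy = classify_hydropathy(res_aa),
    stringsAsFactors = FALSE
  )
  bead_of <- function(res, r) {
    k <- which(beads$residue == res & beads$role == r)
    if (length(k) == 1L) k else NA_integer_
  }

  bi <- integer(0); bj <- integer(0); d0 <- numeric(0); kind <- character(0)
  add <- function(i, j, d, k) {
    if (!is.na(i) && !is.na(j)) {
      bi <<- c(bi, i); bj <<- c(bj, j); d0 <<- c(d0, d); kind <<- c(kind, k)
    }
  }
  bl <- cc$bond_lengths; ps <- cc$pseudo_lengths
  for (i in seq_len(L)) {
    N <- bead_of(i, "N"); CA <- bead_of(i, "CA")
    C <- bead_of(i, "C"); CB <- bead_of(i, "CB")
    add(N, CA, bl[["n_ca"]], "covalent")
    add(CA, C, bl[["ca_c"]], "covalent")
    add(CA, CB, bl[["ca_cb"]], "covalent")
    add(N, C, ps[["n_c"]], "pseudo")
    add(N, CB, ps[["n_cb"]], "pseudo")
    add(C, CB, ps[["c_cb"]], "pseudo")
    if (i < L) {
      Nn <- bead_of(i + 1L, "N"); CAn <- bead_of(i + 1L, "CA")
      add(C, Nn, bl[["c_n"]], "covalent")
      add(CA, Nn, ps[["ca_n"]], "pseudo")
      add(C, CAn, ps[["c_ca"]], "pseudo")
    }
  }
  hw <- ifelse(kind == "covalent", cc$covalent_halfwidth, cc$pseudo_halfwidth)
  bonds <- data.frame(
    i = bi, j = bj, dmin = d0 * (1 - hw), dmax = d0 * (1 + hw),
    kind = kind, stringsAsFactors = FALSE
  )
  stopifnot(all(bonds$dmin < bonds$dmax))

  structure(list(spec = spec, beads = beads, bonds = bonds),
            class = "bead_topology")
}

#' @export
print.bead_topology <- function(x, ...) {
  cat(sprintf("<bead_topology> %s: %d residues, %d beads, %d constraints\n",
              x$spec$isoform_id, x$spec$length, nrow(x$beads), nrow(x$bonds)))
  invisible(x)
}

#' Check that a topology's constraint graph is connected
#'
#' @param topology A `bead_topology`.
#' @return Logical.
#' @export
topology_is_connected <- function(topology) {
  g <- igraph::graph_from_edgelist(
    as.matrix(topology$bonds[, c("i", "j")]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(topology$beads) - igraph::vcount(g)))
  igraph::is_connected(g)
}

#' Read and write sequences as FASTA
#'
#' Minimal FASTA support for peptide specs: one record per peptide.
#'
#' @param specs A list of `peptide_spec` objects.
#' @param path File path.
#' @return `write_fasta` returns `path` invisibly; `read_fasta` a list of
#'   `peptide_spec` objects (isoform id taken from the record name when it
#'   matches a known isoform, `"custom"` otherwise).
#' @export
write_fasta <- function(specs, path) {
  if (inherits(specs, "peptide_spec")) specs <- list(specs)
  lines <- unlist(lapply(specs, function(s) {
    c(paste0(">", s$isoform_id), s$sequence)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records in ", path)
  ends <- c(hdr[-1L] - 1L, length(lines))
  lapply(seq_along(hdr), function(k) {
    name <- sub("^>\\s*", "", lines[hdr[k]])
    name <- strsplit(name, "\\s+")[[1L]][1L]
    seq <- paste(lines[(hdr[k] + 1L):ends[k]], collapse = "")
    if (name %in% names(.isoform_lengths)) {
      sp <- build_sequence(name)
      if (!identical(sp$sequence, toupper(seq))) sp <- build_sequence(seq)
      sp
    } else {
      build_sequence(seq)
    }
  })
}

#' Dump a topology as JSON
#'
#' @param topology A `bead_topology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(topology, path) {
  jsonlite::write_json(
    list(
      isoform_id = topology$spec$isoform_id,
      sequence = topology$spec$sequence,
      beads = topology$beads,
      constraints = topology$bonds
    ),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}
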
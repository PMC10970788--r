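# Molecular graph layer: SMILES handling through OpenBabel (ChemmineOB) and
# a light graph representation (atoms, bonds, implicit hydrogens, ring flags)
# on which the circular fingerprints and graph descriptors are computed.

# default valences used to infer implicit hydrogen counts from a kekulized
# connection table; charge shifts the effective valence for the common
# organic elements (e.g. [NH4+] -> 4, [O-] -> 1)
.DEFAULT_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, As = 3, Se = 2, Br = 1, I = 1
)

# valence (outer-shell) electron counts per element, main groups
.VALENCE_ELECTRONS <- c(
  H = 1, He = 2, Li = 1, Be = 2, B = 3, C = 4, N = 5, O = 6, F = 7, Ne = 8,
  Na = 1, Mg = 2, Al = 3, Si = 4, P = 5, S = 6, Cl = 7, Ar = 8,
  K = 1, Ca = 2, As = 5, Se = 6, Br = 7, Kr = 8, I = 7, Sn = 4, Sb = 5, Te = 6
)

# average atomic masses (IUPAC, rounded)
.ATOMIC_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.99, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, As = 74.922, Se = 78.971, Br = 79.904,
  I = 126.904, Sn = 118.71
)

.ATOMIC_NUMBER <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, As = 33, Se = 34, Br = 35, Kr = 36, I = 53, Sn = 50,
  Sb = 51, Te = 52
)

# Bondi van der Waals radii (Angstrom) and single-bond covalent radii,
# used by the approximate accessible-surface-area descriptor
.VDW_RADIUS <- c(
  H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47, Si = 2.10,
  P = 1.80, S = 1.80, Cl = 1.75, As = 1.85, Se = 1.90, Br = 1.85, I = 1.98
)
.COV_RADIUS <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57, Si = 1.11,
  P = 1.07, S = 1.05, Cl = 1.02, As = 1.19, Se = 1.20, Br = 1.20, I = 1.39
)

#' Canonicalize SMILES strings
#'
#' Converts raw SMILES to canonical SMILES with OpenBabel. Strings OpenBabel
#' cannot parse (including empty strings) are returned as `NA`, which is how
#' the cleaning step identifies unparseable records. OpenBabel stops a batch
#' conversion at the first invalid entry, so the conversion resumes after
#' each failure until every input is accounted for.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of the same length: canonical SMILES, or `NA`
#'   where parsing failed.
#' @export
#' @examples
#' canonical_smiles(c("OCC", "C1CC"))  # "CCO", NA
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  trimmed <- trimws(smiles)
  ok <- !is.na(smiles) & nzchar(trimmed) & !grepl("[[:space:]]", trimmed)
  pending <- which(ok)
  while (length(pending)) {
    tokens <- paste0("gomol", pending)
    input <- paste(paste(trimmed[pending], tokens, sep = "\t"), collapse = "\n")
    res <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", input)),
      error = function(e) ""
    )
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    done <- integer(0)
    if (length(lines)) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      can <- vapply(parts, `[`, "", 1)
      tok <- trimws(vapply(parts, function(p) if (length(p) > 1) p[2] else "", ""))
      hit <- match(tok, tokens)
      good <- !is.na(hit) & nzchar(can)
      out[pending[hit[good]]] <- trimws(can[good])
      done <- hit[good]
    }
    # drop everything already converted plus the first unconverted entry
    # (the one OpenBabel choked on), then retry the rest
    first_bad <- if (length(done)) max(done) + 1L else 1L
    if (first_bad > length(pending)) break
    pending <- pending[-seq_len(first_bad)]
  }
  out
}

#' Parse SMILES into molecular graphs
#'
#' Converts SMILES to kekulized connection tables (via OpenBabel's V2000
#' output) and derives the quantities the fingerprint and descriptor code
#' needs: element symbols, formal charges, implicit hydrogen counts from
#' standard valences, bond orders, heavy-atom degrees and ring membership.
#'
#' @param smiles Character vector of SMILES.
#' @return A list with one element per input: `NULL` where the SMILES does
#'   not parse, otherwise a list with fields `symbol`, `charge`, `nH`,
#'   `bonds` (matrix `a1`, `a2`, `order`), `degree`, `in_ring`, `bond_sum`.
#' @export
parse_molgraph <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- vector("list", length(smiles))
  can <- canonical_smiles(smiles)
  ok <- which(!is.na(can))
  if (!length(ok)) return(out)
  input <- paste(paste(can[ok], paste0("m", seq_along(ok)), sep = "\t"),
                 collapse = "\n")
  sdf_text <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", input)),
    error = function(e) ""
  )
  blocks <- strsplit(sdf_text, "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[grepl("V2000", blocks)]
  for (b in blocks) {
    lines <- strsplit(b, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines) | seq_along(lines) <= 4]
    id <- trimws(lines[1])
    pos <- suppressWarnings(as.integer(sub("^m", "", id)))
    if (is.na(pos) || pos < 1 || pos > length(ok)) next
    g <- tryCatch(.parse_v2000(lines), error = function(e) NULL)
    out[[ok[pos]]] <- g
  }
  out
}

# fixed-width V2000 molfile block -> molecular graph list
.parse_v2000 <- function(lines) {
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  atom_lines <- lines[4 + seq_len(natoms)]
  symbol <- trimws(substr(atom_lines, 32, 34))
  charge <- integer(natoms)
  if (nbonds > 0) {
    bond_lines <- lines[4 + natoms + seq_len(nbonds)]
    bonds <- cbind(a1 = as.integer(substr(bond_lines, 1, 3)),
                   a2 = as.integer(substr(bond_lines, 4, 6)),
                   order = as.integer(substr(bond_lines, 7, 9)))
  } else {
    bonds <- matrix(integer(0), ncol = 3,
                    dimnames = list(NULL, c("a1", "a2", "order")))
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[[:space:]]+")[[1]])
    npairs <- f[1]
    for (j in seq_len(npairs)) {
      charge[f[2 * j]] <- f[2 * j + 1]
    }
  }
  # fold explicit hydrogens (rare in OpenBabel SMILES output) into parents
  is_h <- symbol == "H"
  nH_explicit <- integer(natoms)
  if (any(is_h)) {
    keep <- which(!is_h)
    remap <- match(seq_len(natoms), keep)
    keep_rows <- logical(nrow(bonds))
    for (r in seq_len(nrow(bonds))) {
      a1 <- bonds[r, 1]; a2 <- bonds[r, 2]
      if (is_h[a1] && !is_h[a2]) nH_explicit[a2] <- nH_explicit[a2] + 1L
      else if (is_h[a2] && !is_h[a1]) nH_explicit[a1] <- nH_explicit[a1] + 1L
      else if (!is_h[a1] && !is_h[a2]) keep_rows[r] <- TRUE
    }
    bonds <- bonds[keep_rows, , drop = FALSE]
    bonds[, 1] <- remap[bonds[, 1]]; bonds[, 2] <- remap[bonds[, 2]]
    symbol <- symbol[keep]; charge <- charge[keep]
    nH_explicit <- nH_explicit[keep]
    natoms <- length(symbol)
  }
  bond_sum <- numeric(natoms); degree <- integer(natoms)
  for (r in seq_len(nrow(bonds))) {
    a1 <- bonds[r, 1]; a2 <- bonds[r, 2]; o <- bonds[r, 3]
    bond_sum[a1] <- bond_sum[a1] + o; bond_sum[a2] <- bond_sum[a2] + o
    degree[a1] <- degree[a1] + 1L; degree[a2] <- degree[a2] + 1L
  }
  val <- unname(.DEFAULT_VALENCE[symbol])
  val[is.na(val)] <- 0
  eff <- val
  shift <- symbol %in% c("N", "P", "O", "S", "B")
  eff[shift] <- eff[shift] + charge[shift]
  isC <- symbol == "C"
  eff[isC] <- eff[isC] - abs(charge[isC])
  nH <- pmax(0, round(eff - bond_sum)) + nH_explicit
  rings <- .ring_flags(natoms, bonds)
  list(symbol = symbol, charge = as.integer(charge), nH = as.integer(nH),
       bonds = bonds, degree = degree,
       in_ring = rings$atoms, bond_in_ring = rings$bonds,
       bond_sum = bond_sum)
}

# an atom/bond lies on a cycle iff the bond is not a bridge
.ring_flags <- function(n, bonds) {
  atom_ring <- rep(FALSE, n)
  bond_ring <- rep(FALSE, nrow(bonds))
  if (!nrow(bonds)) return(list(atoms = atom_ring, bonds = bond_ring))
  g <- igraph::graph_from_edgelist(cbind(bonds[, 1], bonds[, 2]), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  br <- igraph::bridges(g)
  cyc <- setdiff(seq_len(nrow(bonds)), as.integer(br))
  if (length(cyc)) {
    bond_ring[cyc] <- TRUE
    atom_ring[unique(c(bonds[cyc, 1], bonds[cyc, 2]))] <- TRUE
  }
  list(atoms = atom_ring, bonds = bond_ring)
}
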
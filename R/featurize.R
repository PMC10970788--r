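# Circular (Morgan/ECFP-style) fingerprints, Dice similarity and the
# physicochemical descriptor battery.

#' Morgan circular fingerprint of one molecule
#'
#' Computes an ECFP-style circular fingerprint: every atom receives an
#' initial invariant hashed from (atomic number, heavy degree, implicit H
#' count, formal charge, ring flag); the invariant is then iteratively
#' re-hashed with the sorted (bond order, neighbour invariant) pairs up to
#' the requested radius. Environments that duplicate an already-emitted
#' environment (identical bond set) are dropped, and the surviving
#' identifiers are folded modulo `nbits` into a binary vector.
#'
#' @param smiles A single SMILES string (canonical or not; it is parsed
#'   through the same canonicalization as the rest of the package).
#' @param radius Neighbourhood radius in bonds (default 2).
#' @param nbits Folded fingerprint length (default 2048).
#' @return An object of class `morgan_fp`: list with `bits` (0/1 integer
#'   vector of length `nbits`), `on_bits` (sorted 1-based positions),
#'   `radius`, `nbits`, and `n_env` (cumulative count of distinct
#'   environments at each radius 0..`radius`).
#' @export
#' @examples
#' fp <- morgan_fingerprint("CCO")
#' length(fp$on_bits)
morgan_fingerprint <- function(smiles, radius = 2, nbits = 2048) {
  stopifnot(length(smiles) == 1)
  g <- parse_molgraph(smiles)[[1]]
  if (is.null(g)) stop2("cannot compute fingerprint: unparseable SMILES '%s'", smiles)
  .morgan_from_graph(g, radius = radius, nbits = nbits)
}

#' Morgan fingerprints for a vector of molecules
#'
#' @param smiles Character vector of SMILES.
#' @param radius,nbits As in [morgan_fingerprint()].
#' @return A list with `matrix` (molecules x `nbits` 0/1 integer matrix,
#'   rownames from `names(smiles)`), `density` (molecules x (radius+1)
#'   matrix of distinct-environment counts per heavy atom at radius
#'   0..radius), and `failed` (indices of unparseable inputs, whose rows
#'   are `NA`).
#' @export
morgan_fingerprints <- function(smiles, radius = 2, nbits = 2048) {
  graphs <- parse_molgraph(smiles)
  n <- length(graphs)
  m <- matrix(NA_integer_, n, nbits)
  dens <- matrix(NA_real_, n, radius + 1,
                 dimnames = list(NULL, paste0("r", 0:radius)))
  failed <- integer(0)
  for (i in seq_len(n)) {
    if (is.null(graphs[[i]])) { failed <- c(failed, i); next }
    fp <- .morgan_from_graph(graphs[[i]], radius = radius, nbits = nbits)
    m[i, ] <- fp$bits
    dens[i, ] <- fp$n_env / length(graphs[[i]]$symbol)
  }
  if (!is.null(names(smiles))) rownames(m) <- names(smiles)
  list(matrix = m, density = dens, failed = failed)
}

.morgan_from_graph <- function(g, radius = 2, nbits = 2048) {
  n <- length(g$symbol)
  z <- unname(.ATOMIC_NUMBER[g$symbol]); z[is.na(z)] <- 0
  inv <- vapply(seq_len(n), function(a) {
    hash_mix(c(z[a], g$degree[a], g$nH[a], g$charge[a] + 8, as.integer(g$in_ring[a])))
  }, 0)
  ids <- inv
  n_env <- numeric(radius + 1)
  n_env[1] <- length(unique(ids))
  if (radius > 0 && n >= 1) {
    nb <- vector("list", n)     # per atom: matrix (neighbour, order)
    for (r in seq_len(nrow(g$bonds))) {
      a1 <- g$bonds[r, 1]; a2 <- g$bonds[r, 2]; o <- g$bonds[r, 3]
      nb[[a1]] <- rbind(nb[[a1]], c(a2, o))
      nb[[a2]] <- rbind(nb[[a2]], c(a1, o))
    }
    dmat <- .bond_bfs_dist(n, nb)
    seen <- character(0)
    for (r in seq_len(radius)) {
      new_inv <- inv
      for (a in seq_len(n)) {
        if (is.null(nb[[a]])) next
        pairs <- cbind(nb[[a]][, 2], inv[nb[[a]][, 1]])
        ord <- order(pairs[, 1], pairs[, 2])
        new_inv[a] <- hash_mix(c(inv[a], t(pairs[ord, , drop = FALSE])))
      }
      # emit in invariant order; drop environments whose bond set was seen
      if (nrow(g$bonds)) {
        env_keys <- vapply(seq_len(n), function(a) {
          ends_near <- dmat[a, g$bonds[, 1]] <= r - 1 | dmat[a, g$bonds[, 2]] <= r - 1
          paste(which(ends_near), collapse = ",")
        }, "")
        for (a in order(new_inv, seq_len(n))) {
          k <- env_keys[a]
          if (!nzchar(k) || k %in% seen) next
          seen <- c(seen, k)
          ids <- c(ids, new_inv[a])
        }
      }
      inv <- new_inv
      n_env[r + 1] <- length(unique(ids))
    }
  } else if (radius > 0) {
    n_env[seq_len(radius) + 1] <- n_env[1]
  }
  if (radius > 0) {
    # radii past the molecule's diameter add nothing
    n_env[-1][n_env[-1] == 0] <- n_env[1]
    for (r in seq_len(radius)) {
      if (n_env[r + 1] < n_env[r]) n_env[r + 1] <- n_env[r]
    }
  }
  bits <- integer(nbits)
  bits[unique(ids) %% nbits + 1] <- 1L
  structure(list(bits = bits, on_bits = sort(unique(unique(ids) %% nbits + 1)),
                 radius = radius, nbits = nbits, n_env = n_env),
            class = "morgan_fp")
}

# all-pairs bond-count distances by BFS (molecules are small)
.bond_bfs_dist <- function(n, nb) {
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer(0)
      for (a in frontier) {
        if (is.null(nb[[a]])) next
        for (b in nb[[a]][, 1]) {
          if (d[s, b] > depth) { d[s, b] <- depth; nxt <- c(nxt, b) }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

#' Dice similarity between two fingerprints
#'
#' `DSC(A, B) = 2 |X ∩ Y| / (|X| + |Y|)` where `X`, `Y` are the on-bit sets
#' of the two fingerprints. Two empty fingerprints are defined to have
#' similarity 0 (with a warning) rather than 1, so featureless inputs are
#' never spuriously identical.
#'
#' @param a,b `morgan_fp` objects, or plain 0/1 vectors of equal length.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' dice_similarity(morgan_fingerprint("CCO"), morgan_fingerprint("CCCO"))
dice_similarity <- function(a, b) {
  xa <- if (inherits(a, "morgan_fp")) a$on_bits else which(a != 0)
  xb <- if (inherits(b, "morgan_fp")) b$on_bits else which(b != 0)
  if (length(xa) == 0 && length(xb) == 0) {
    warn2("both fingerprints are empty; Dice similarity defined as 0")
    return(0)
  }
  2 * length(intersect(xa, xb)) / (length(xa) + length(xb))
}

#' Pairwise Dice similarity matrix
#'
#' @param m Molecules x bits 0/1 matrix.
#' @return Symmetric molecules x molecules matrix of Dice similarities
#'   (pairs of all-zero rows get 0).
#' @export
dice_matrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  inter <- tcrossprod(m)
  s <- rowSums(m)
  denom <- outer(s, s, "+")
  out <- ifelse(denom > 0, 2 * inter / denom, 0)
  diag(out) <- ifelse(s > 0, 1, 0)
  out
}

# descriptor battery column order (the nine screening descriptors first)
.MANDATORY_DESCRIPTORS <- c(
  "FpDensityMorgan1", "FpDensityMorgan2", "FpDensityMorgan3",
  "NumValenceElectrons", "MolWt", "PSA", "pyLabuteASA",
  "HeavyAtomMolWt", "TPSA"
)

#' Physicochemical descriptor battery
#'
#' Computes a named descriptor vector per molecule. The battery always
#' contains the nine descriptors used by the factor screening
#' (`FpDensityMorgan1`-`3`, `NumValenceElectrons`, `MolWt`, `PSA`,
#' `pyLabuteASA`, `HeavyAtomMolWt`, `TPSA`) plus additional standard
#' properties (logP, molar refractivity, H-bond donors/acceptors, ring and
#' rotatable-bond counts, ...). `PSA` and `TPSA` are both topological polar
#' surface areas and are kept as two named entries because descriptor
#' batteries conventionally list both labels. Molecular weights are summed
#' from standard average atomic masses including implicit hydrogens;
#' `pyLabuteASA` is Labute's approximate accessible surface area computed
#' from Bondi radii with spherical-cap overlap removal.
#'
#' @param smiles Character vector of SMILES.
#' @return A data.frame (one row per molecule) with a `failed` attribute
#'   listing indices of molecules the engine could not process; those rows
#'   are `NA` and a warning is emitted.
#' @export
#' @examples
#' compute_descriptors("CCO")[, c("MolWt", "NumValenceElectrons", "TPSA")]
compute_descriptors <- function(smiles) {
  graphs <- parse_molgraph(smiles)
  n <- length(graphs)
  fps <- morgan_fingerprints(smiles, radius = 3, nbits = 2048)
  cols <- c(.MANDATORY_DESCRIPTORS,
            "MolLogP", "MolMR", "NumHAcceptors", "NumHDonors",
            "HeavyAtomCount", "RingCount", "NumRotatableBonds",
            "NumHeteroatoms", "FractionCSP3")
  out <- as.data.frame(matrix(NA_real_, n, length(cols),
                              dimnames = list(names(smiles), cols)))
  ob <- .propob_safe(smiles, graphs)
  failed <- integer(0)
  for (i in seq_len(n)) {
    g <- graphs[[i]]
    if (is.null(g)) { failed <- c(failed, i); next }
    mass <- unname(.ATOMIC_MASS[g$symbol])
    velec <- unname(.VALENCE_ELECTRONS[g$symbol])
    if (anyNA(mass) || anyNA(velec)) { failed <- c(failed, i); next }
    nH_tot <- sum(g$nH)
    molwt <- sum(mass) + nH_tot * .ATOMIC_MASS[["H"]]
    tpsa <- ob$TPSA[i]
    if (is.na(tpsa)) tpsa <- 0
    out[i, "MolWt"] <- molwt
    out[i, "HeavyAtomMolWt"] <- sum(mass)
    out[i, "NumValenceElectrons"] <- sum(velec) + nH_tot - sum(g$charge)
    out[i, "TPSA"] <- tpsa
    out[i, "PSA"] <- tpsa
    out[i, "pyLabuteASA"] <- .labute_asa(g)
    out[i, c("FpDensityMorgan1", "FpDensityMorgan2", "FpDensityMorgan3")] <-
      fps$density[i, c("r1", "r2", "r3")]
    out[i, "MolLogP"] <- ob$logP[i]
    out[i, "MolMR"] <- ob$MR[i]
    out[i, "NumHAcceptors"] <- ob$HBA1[i]
    out[i, "NumHDonors"] <- ob$HBD[i]
    out[i, "HeavyAtomCount"] <- length(g$symbol)
    ncomp <- .n_components(length(g$symbol), g$bonds)
    out[i, "RingCount"] <- nrow(g$bonds) - length(g$symbol) + ncomp
    out[i, "NumRotatableBonds"] <- .n_rotatable(g)
    out[i, "NumHeteroatoms"] <- sum(!g$symbol %in% c("C", "H"))
    isC <- g$symbol == "C"
    out[i, "FractionCSP3"] <- if (any(isC)) {
      sp3 <- isC & (g$bond_sum - g$degree) == 0   # no multiple bonds
      sum(sp3) / sum(isC)
    } else 0
  }
  if (length(failed)) {
    warn2("descriptor engine failed on %d molecule(s) (indices %s); rows set to NA",
          length(failed), paste(utils::head(failed, 10), collapse = ", "))
  }
  attr(out, "failed") <- failed
  out
}

# OpenBabel bulk properties; single-heavy-atom molecules are skipped by the
# SDF container (their TPSA/logP fall back to 0/NA)
.propob_safe <- function(smiles, graphs) {
  n <- length(smiles)
  res <- data.frame(TPSA = rep(NA_real_, n), logP = NA_real_,
                    MR = NA_real_, HBA1 = NA_real_, HBD = NA_real_)
  multi <- which(vapply(graphs, function(g) !is.null(g) && length(g$symbol) >= 2, TRUE))
  if (!length(multi)) return(res)
  can <- canonical_smiles(smiles[multi])
  smis <- can; names(smis) <- paste0("m", seq_along(multi))
  pr <- tryCatch({
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(smis))
    p <- suppressWarnings(ChemmineR::propOB(sdf))
    p$.idx <- as.integer(sub("^m", "", p$title))
    p
  }, error = function(e) NULL)
  if (is.null(pr)) return(res)
  for (col in c("TPSA", "logP", "MR", "HBA1", "HBD")) {
    if (col %in% names(pr)) res[[col]][multi[pr$.idx]] <- as.numeric(pr[[col]])
  }
  res
}

.n_components <- function(n, bonds) {
  if (!nrow(bonds)) return(n)
  g <- igraph::graph_from_edgelist(cbind(bonds[, 1], bonds[, 2]), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::components(g)$no
}

# single, acyclic bonds between two non-terminal heavy atoms
.n_rotatable <- function(g) {
  if (!nrow(g$bonds)) return(0L)
  sum(g$bonds[, 3] == 1 & !g$bond_in_ring &
        g$degree[g$bonds[, 1]] >= 2 & g$degree[g$bonds[, 2]] >= 2)
}

# Labute's approximate accessible surface area (Angstrom^2): full van der
# Waals sphere per atom (implicit hydrogens included as explicit spheres)
# minus one spherical cap per bonded neighbour at the idealised bond length
.labute_asa <- function(g) {
  rvdw <- function(sym) { r <- .VDW_RADIUS[sym]; ifelse(is.na(r), 1.7, r) }
  rcov <- function(sym) { r <- .COV_RADIUS[sym]; ifelse(is.na(r), 0.77, r) }
  shorten <- c(1, 0.92, 0.87, 0.87)  # bond-order contraction of ideal length
  cap <- function(Ri, Rj, d) {
    if (d >= Ri + Rj) return(0)
    d <- max(d, abs(Ri - Rj) + 0.01)
    x <- (d^2 + Ri^2 - Rj^2) / (2 * d)
    h <- min(max(Ri - x, 0), 2 * Ri)
    2 * pi * Ri * h
  }
  total <- 0
  n <- length(g$symbol)
  for (a in seq_len(n)) {
    Ra <- rvdw(g$symbol[a])
    area <- 4 * pi * Ra^2
    if (nrow(g$bonds)) {
      for (r in which(g$bonds[, 1] == a | g$bonds[, 2] == a)) {
        b <- if (g$bonds[r, 1] == a) g$bonds[r, 2] else g$bonds[r, 1]
        d <- (rcov(g$symbol[a]) + rcov(g$symbol[b])) * shorten[min(g$bonds[r, 3], 4)]
        area <- area - cap(Ra, rvdw(g$symbol[b]), d)
      }
    }
    dH <- rcov(g$symbol[a]) + .COV_RADIUS[["H"]]
    area <- area - g$nH[a] * cap(Ra, .VDW_RADIUS[["H"]], dH)
    total <- total + max(area, 0)
    # hydrogen spheres, shadowed by their parent only
    if (g$nH[a] > 0) {
      ha <- 4 * pi * .VDW_RADIUS[["H"]]^2 - cap(.VDW_RADIUS[["H"]], Ra, dH)
      total <- total + g$nH[a] * max(ha, 0)
    }
  }
  total
}

#' Write fingerprints as hex-encoded text
#'
#' One line per molecule: name, tab, the bit vector packed into hex
#' (4 bits per character, most significant first).
#'
#' @param fps Result of [morgan_fingerprints()] or a 0/1 matrix.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_fingerprints <- function(fps, path) {
  m <- if (is.list(fps)) fps$matrix else fps
  stopifnot(is.matrix(m))
  nm <- rownames(m) %||% paste0("mol", seq_len(nrow(m)))
  hex <- apply(m, 1, function(bits) {
    bits[is.na(bits)] <- 0L
    nib <- matrix(bits, nrow = 4)
    paste(sprintf("%x", colSums(nib * c(8, 4, 2, 1))), collapse = "")
  })
  writeLines(paste(nm, hex, sep = "\t"), path)
  invisible(path)
}
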
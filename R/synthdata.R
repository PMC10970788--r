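# Synthetic labelled SMILES generation. The green class emulates the
# short-chain aliphatic alcohol/aldehyde/ester/ketone chemotype of leaf
# volatiles (hexenols/hexenals and their homologues, chain lengths 4-10,
# E/Z unsaturation); the non-green class is built from larger aromatic,
# heteroatom-rich scaffolds. By construction the green class has lower
# molecular weight, fewer valence electrons, lower polar surface area and
# denser circular fingerprints - the contrasts the difference analysis is
# expected to recover.

.CHAIN_NAMES <- c(`4` = "but", `5` = "pent", `6` = "hex", `7` = "hept",
                  `8` = "oct", `9` = "non", `10` = "dec")

# enumerate the green template family; returns data.frame(name, smiles)
.green_templates <- function(chain_lengths = 4:10) {
  rows <- list()
  add <- function(name, smiles, family) {
    rows[[length(rows) + 1]] <<- data.frame(name = name, smiles = smiles,
                                            family = family)
  }
  for (n in chain_lengths) {
    cn <- .CHAIN_NAMES[[as.character(n)]]
    variants <- list(list(tag = "sat", p = 0, s = ""))
    for (p in 2:(n - 2)) {
      for (s in c("Z", "E")) {
        variants[[length(variants) + 1]] <- list(tag = sprintf("%d%s", p, s), p = p, s = s)
      }
    }
    chain_after <- function(from, p, s) {
      # carbons from position `from` to n with optional stereo double bond
      # p/p+1; the "/" stereo marker rides on the bond into carbon p, whose
      # left neighbour (head atom or previous chain carbon) already exists
      if (p == 0 || p < from) return(strrep("C", n - from + 1))
      pre <- strrep("C", p - from)
      db <- if (s == "Z") "/C=C\\" else "/C=C/"
      paste0(pre, db, strrep("C", n - p - 1))
    }
    for (v in variants) {
      p <- v$p; s <- v$s
      if (p >= 2) {
        add(sprintf("%s-%s-en-1-ol", cn, v$tag), paste0("OC", chain_after(2, p, s)),
            "alcohol")
        add(sprintf("%s-%s-enal", cn, v$tag), paste0("O=C", chain_after(2, p, s)),
            "aldehyde")
        add(sprintf("%s-%s-enyl acetate", cn, v$tag),
            paste0("CC(=O)OC", chain_after(2, p, s)), "ester")
        if (p >= 3) {
          add(sprintf("%s-%s-en-2-one", cn, v$tag),
              paste0("CC(=O)", chain_after(3, p, s)), "ketone")
        }
      } else {
        add(sprintf("%san-1-ol", cn), paste0("OC", strrep("C", n - 1)), "alcohol")
        add(sprintf("%sanal", cn), paste0("O=C", strrep("C", n - 1)), "aldehyde")
        add(sprintf("%syl acetate", cn), paste0("CC(=O)OC", strrep("C", n - 1)), "ester")
        add(sprintf("%san-2-one", cn), paste0("CC(=O)", strrep("C", n - 2)), "ketone")
        add(sprintf("methyl %sanoate", cn), paste0("COC(=O)", strrep("C", n - 1)), "ester")
      }
    }
  }
  do.call(rbind, rows)
}

# aromatic / heteroatom-rich non-green family: tri-substituted benzenes and
# di-substituted fused bicyclics carrying polar substituents, so the class
# sits well above the green family in mass and polar surface area
.nongreen_templates <- function() {
  subs <- c(hydroxy = "O", methoxy = "OC", ethoxy = "OCC",
            nitro = "[N+](=O)[O-]", carboxy = "C(=O)O",
            ester = "C(=O)OC", amide = "C(=O)N", amino = "N",
            acetamido = "NC(C)=O", sulfamoyl = "S(=O)(=O)N",
            chloro = "Cl", bromo = "Br", cyano = "C#N", acetyl = "C(=O)C")
  cores3 <- c(benzene = "c1c(%s)cc(%s)cc1%s")
  cores2 <- c(naphthalene = "c1c(%s)ccc2cc(%s)ccc12",
              quinoline = "c1c(%s)ccc2nc(%s)ccc12",
              benzofuran = "c1c(%s)ccc2c1cc(o2)%s",
              benzothiophene = "c1c(%s)ccc2c1cc(s2)%s")
  rows <- list()
  for (i in names(subs)) {
    for (j in names(subs)) {
      for (k in names(subs)) {
        rows[[length(rows) + 1]] <- data.frame(
          name = sprintf("ng benzene %s/%s/%s", i, j, k),
          smiles = sprintf(cores3[["benzene"]], subs[[i]], subs[[j]], subs[[k]]))
      }
    }
  }
  for (cname in names(cores2)) {
    for (i in names(subs)) {
      for (j in names(subs)) {
        rows[[length(rows) + 1]] <- data.frame(
          name = sprintf("ng %s %s/%s", cname, i, j),
          smiles = sprintf(cores2[[cname]], subs[[i]], subs[[j]]))
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic labelled odorant dataset
#'
#' Draws `n_green` molecules from the aliphatic green-odorant template
#' family and `n_nongreen` from the aromatic non-green family, without
#' duplicate canonical SMILES within a class, deterministically for a given
#' seed. The returned dataset carries a `report` attribute with the
#' realized per-class means of molecular weight and polar surface area.
#'
#' The green family carries a head-group chemotype tag (`alcohol`,
#' `aldehyde`, `ester`, `ketone`); `green_families` restricts the draw to a
#' subset of chemotypes, sampling each in (near-)equal proportion, which is
#' how multi-chemotype cluster-recovery fixtures are built.
#'
#' @param n_green,n_nongreen Class sizes (each at least 1).
#' @param seed Integer seed.
#' @param report Compute the realized-property generation report (default
#'   TRUE; involves descriptor computation).
#' @param green_families Optional character subset of
#'   `c("alcohol", "aldehyde", "ester", "ketone")`.
#' @return An `odor_dataset` (columns name, smiles_raw, smiles_canonical,
#'   label) with attribute `report`; green rows also carry their chemotype
#'   in attribute `green_family`.
#' @export
#' @examples
#' \donttest{
#' ds <- generate_synthetic(20, 20, seed = 1)
#' attr(ds, "report")
#' }
generate_synthetic <- function(n_green, n_nongreen, seed = 1, report = TRUE,
                               green_families = NULL) {
  stopifnot(n_green >= 1, n_nongreen >= 1)
  dedupe <- function(templates) {
    can <- canonical_smiles(templates$smiles)
    ok <- !is.na(can) & !duplicated(can)
    pool <- templates[ok, , drop = FALSE]
    pool$can <- can[ok]
    pool
  }
  pick <- function(pool, n, cls, stage) {
    if (n > nrow(pool)) {
      stop2("requested %d %s molecules but only %d distinct templates exist",
            n, cls, nrow(pool))
    }
    sel <- with_local_seed(derive_seed(seed, stage),
                           sample.int(nrow(pool), n))
    pool[sort(sel), , drop = FALSE]
  }
  gpool <- dedupe(.green_templates())
  if (!is.null(green_families)) {
    stopifnot(all(green_families %in% unique(gpool$family)))
    per <- diff(round(seq(0, n_green, length.out = length(green_families) + 1)))
    g <- do.call(rbind, lapply(seq_along(green_families), function(i) {
      pick(gpool[gpool$family == green_families[i], , drop = FALSE],
           per[i], paste0("green/", green_families[i]),
           paste0("synth-green-", green_families[i]))
    }))
  } else {
    g <- pick(gpool, n_green, "green", "synth-green")
  }
  ng <- pick(dedupe(.nongreen_templates()), n_nongreen, "nongreen",
             "synth-nongreen")
  ds <- odor_dataset(c(g$name, ng$name), c(g$can, ng$can),
                     c(rep("green", nrow(g)), rep("nongreen", nrow(ng))),
                     provenance = sprintf(
                       "synthetic templates (%d green, %d nongreen, seed %d)",
                       n_green, n_nongreen, as.integer(seed)))
  ds$smiles_canonical <- c(g$can, ng$can)
  attr(ds, "green_family") <- g$family
  if (report) {
    desc <- compute_descriptors(stats::setNames(ds$smiles_canonical, ds$name))
    green <- ds$label == "green"
    attr(ds, "report") <- list(
      mean_molwt = c(green = mean(desc$MolWt[green], na.rm = TRUE),
                     nongreen = mean(desc$MolWt[!green], na.rm = TRUE)),
      mean_tpsa = c(green = mean(desc$TPSA[green], na.rm = TRUE),
                    nongreen = mean(desc$TPSA[!green], na.rm = TRUE)))
  }
  ds
}

#' Linearly separable synthetic fingerprints
#'
#' Class "nongreen" draws its on-bits from the lower half of the bit
#' positions, class "green" from the upper half; each class has one anchor
#' bit that is always set. At `noise = 0` the construction is linearly
#' separable and the anchor bit alone classifies perfectly; with
#' `noise > 0` each non-anchor bit is relocated into the wrong half with
#' that probability.
#'
#' @param n_per_class Molecules per class.
#' @param nbits Fingerprint length (at least 16; default 2048).
#' @param n_on Number of on-bits drawn per molecule (default 32).
#' @param noise Per-bit relocation probability (default 0).
#' @param seed Integer seed.
#' @return A list with `X` (2 n_per_class x nbits 0/1 matrix), `y`
#'   (character labels), `anchors` (the two anchor bit positions).
#' @export
generate_separable_fingerprints <- function(n_per_class, nbits = 2048,
                                            n_on = 32, noise = 0, seed = 1) {
  stopifnot(nbits >= 16, n_per_class >= 1, n_on >= 2, noise >= 0, noise <= 1)
  half <- nbits %/% 2
  anchors <- c(nongreen = 1L, green = half + 1L)
  with_local_seed(derive_seed(seed, "separable-fp"), {
    draw <- function(lo, hi, anchor, other_lo, other_hi) {
      bits <- integer(nbits)
      bits[anchor] <- 1L
      pool <- setdiff(lo:hi, anchor)
      on <- sample(pool, n_on - 1)
      if (noise > 0) {
        flip <- stats::runif(length(on)) < noise
        if (any(flip)) {
          on[flip] <- sample(other_lo:other_hi, sum(flip), replace = TRUE)
        }
      }
      bits[unique(on)] <- 1L
      bits
    }
    X <- rbind(
      t(vapply(seq_len(n_per_class), function(i) {
        draw(1, half, anchors[["nongreen"]], half + 1, nbits)
      }, integer(nbits))),
      t(vapply(seq_len(n_per_class), function(i) {
        draw(half + 1, nbits, anchors[["green"]], 1, half)
      }, integer(nbits)))
    )
    list(X = X, y = c(rep("nongreen", n_per_class), rep("green", n_per_class)),
         anchors = anchors)
  })
}
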
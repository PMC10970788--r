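# Dataset I/O, cleaning, balancing and cross-validation splits.
#
# A dataset is a plain data.frame with columns
#   name, smiles_raw, smiles_canonical, label
# where label is "green" or "nongreen", plus a "provenance" attribute
# carrying free-text processing history.

.LABEL_LEVELS <- c("green", "nongreen")

#' Construct an odor dataset
#'
#' @param name Character vector of molecule names.
#' @param smiles Character vector of raw SMILES.
#' @param label Character vector of class labels; case-insensitive variants
#'   of "green" and "nongreen"/"non-green"/"non_green" are normalized.
#' @param provenance Free-text provenance note.
#' @return A data.frame of class `odor_dataset` with columns `name`,
#'   `smiles_raw`, `smiles_canonical` (NA until [clean_dataset()]), `label`.
#' @export
odor_dataset <- function(name, smiles, label, provenance = "constructed in R") {
  stopifnot(length(name) == length(smiles), length(smiles) == length(label))
  lab <- normalize_label(label)
  bad <- which(is.na(lab))
  if (length(bad)) {
    stop2("unknown label token '%s' at record %d (expected green/nongreen)",
          label[bad[1]], bad[1])
  }
  ds <- data.frame(name = as.character(name),
                   smiles_raw = as.character(smiles),
                   smiles_canonical = NA_character_,
                   label = lab,
                   stringsAsFactors = FALSE)
  attr(ds, "provenance") <- provenance
  class(ds) <- c("odor_dataset", "data.frame")
  ds
}

#' Normalize class label tokens
#'
#' @param label Character vector.
#' @return Character vector with values "green"/"nongreen", NA for unknown
#'   tokens.
#' @export
normalize_label <- function(label) {
  x <- tolower(trimws(as.character(label)))
  x <- gsub("[-_ ]", "", x)
  out <- rep(NA_character_, length(x))
  out[x %in% c("green", "g", "positive", "1")] <- "green"
  out[x %in% c("nongreen", "notgreen", "negative", "0")] <- "nongreen"
  out
}

#' Read a labelled molecule table
#'
#' Reads a CSV (or TSV, chosen by file extension or `sep`) with one molecule
#' per row. Column names are mapped through `col_map` so exports from
#' heterogeneous source databases can be consumed directly.
#'
#' @param path File path.
#' @param col_map Named character vector mapping the canonical column roles
#'   `name`, `smiles`, `label` to the header names present in the file.
#' @param sep Field separator; default chosen from the file extension
#'   (`.tsv`/`.smi` tab, otherwise comma).
#' @return An `odor_dataset`.
#' @export
read_dataset <- function(path, col_map = c(name = "name", smiles = "smiles",
                                           label = "label"), sep = NULL) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  sep <- sep %||% if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          check.names = FALSE)
  need <- col_map[c("name", "smiles", "label")]
  miss <- need[!need %in% names(df)]
  if (length(miss)) {
    stop2("missing column(s) %s in %s (header: %s)",
          paste(sQuote(miss), collapse = ", "), path,
          paste(names(df), collapse = ", "))
  }
  lab <- normalize_label(df[[need[["label"]]]])
  bad <- which(is.na(lab))
  if (length(bad)) {
    stop2("unknown label token '%s' at line %d of %s",
          df[[need[["label"]]]][bad[1]], bad[1] + 1L, path)
  }
  ds <- odor_dataset(df[[need[["name"]]]], df[[need[["smiles"]]]], lab,
                     provenance = sprintf("read from %s (%d records)", path, nrow(df)))
  if ("smiles_canonical" %in% names(df)) {
    ds$smiles_canonical <- as.character(df$smiles_canonical)
  }
  ds
}

#' Read a SMI file (one "SMILES name" pair per line)
#'
#' @param path File path.
#' @param label Label to assign to every record.
#' @return An `odor_dataset`.
#' @export
read_smi <- function(path, label) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  smiles <- vapply(parts, `[`, "", 1)
  nm <- vapply(parts, function(p) if (length(p) > 1) paste(p[-1], collapse = " ") else "", "")
  nm[!nzchar(nm)] <- paste0("mol", which(!nzchar(nm)))
  odor_dataset(nm, smiles, rep(label, length(smiles)),
               provenance = sprintf("read from %s (%d records)", path, length(smiles)))
}

#' Write a dataset as CSV
#'
#' Writes columns `name`, `smiles`, `label` (and `smiles_canonical` if the
#' dataset has been cleaned), so a write/read round trip is the identity on
#' (name, smiles_raw, label).
#'
#' @param ds An `odor_dataset`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "odor_dataset"))
  out <- data.frame(name = ds$name, smiles = ds$smiles_raw, label = ds$label,
                    stringsAsFactors = FALSE)
  if (!all(is.na(ds$smiles_canonical))) out$smiles_canonical <- ds$smiles_canonical
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Clean a molecule dataset
#'
#' Canonicalizes every SMILES, drops records the chemistry engine cannot
#' parse (an empty SMILES counts as unparseable, not as an error), and
#' removes exact canonical-SMILES duplicates keeping the first occurrence.
#' The drop counts are recorded in the dataset's provenance attribute and
#' as attributes `dropped_unparseable` / `dropped_duplicate`.
#'
#' @param raw An `odor_dataset`.
#' @return The cleaned `odor_dataset` (every record has a valid
#'   `smiles_canonical`; canonical SMILES are unique).
#' @export
clean_dataset <- function(raw) {
  stopifnot(inherits(raw, "odor_dataset"))
  if (nrow(raw) == 0) stop2("cannot clean an empty dataset")
  can <- canonical_smiles(raw$smiles_raw)
  parseable <- !is.na(can)
  n_unparse <- sum(!parseable)
  keep <- which(parseable)
  dup <- duplicated(can[keep])
  n_dup <- sum(dup)
  keep <- keep[!dup]
  out <- raw[keep, , drop = FALSE]
  out$smiles_canonical <- can[keep]
  rownames(out) <- NULL
  prov <- sprintf(
    "%s | cleaned: %d in, %d dropped-unparseable, %d dropped-duplicate, %d retained",
    attr(raw, "provenance") %||% "", nrow(raw), n_unparse, n_dup, nrow(out))
  attr(out, "provenance") <- prov
  attr(out, "dropped_unparseable") <- n_unparse
  attr(out, "dropped_duplicate") <- n_dup
  class(out) <- c("odor_dataset", "data.frame")
  out
}

#' Down-sample a majority class preserving its property distribution
#'
#' Samples exactly `target_n` records without replacement, stratified over
#' quartile bins of molecular weight, so the molecular-weight distribution
#' of the majority class is preserved. Class labels are never inspected.
#'
#' @param majority An `odor_dataset` (typically the majority class after
#'   cleaning).
#' @param target_n Number of records to keep; must not exceed the input
#'   size.
#' @param seed Integer seed; the selection is deterministic given the seed.
#' @return An `odor_dataset` with `target_n` records in original relative
#'   order.
#' @export
balance_majority <- function(majority, target_n, seed) {
  stopifnot(inherits(majority, "odor_dataset"))
  n <- nrow(majority)
  if (target_n > n) {
    stop2("target_n (%d) exceeds majority size (%d); balancing only reduces",
          target_n, n)
  }
  if (target_n == n) return(majority)
  smi <- ifelse(is.na(majority$smiles_canonical), majority$smiles_raw,
                majority$smiles_canonical)
  graphs <- parse_molgraph(smi)
  mw <- vapply(graphs, function(g) {
    if (is.null(g)) return(NA_real_)
    mass <- .ATOMIC_MASS[g$symbol]
    sum(mass, na.rm = TRUE) + sum(g$nH) * .ATOMIC_MASS[["H"]]
  }, 0)
  mw[is.na(mw)] <- stats::median(mw, na.rm = TRUE)
  qs <- stats::quantile(mw, c(0.25, 0.5, 0.75), names = FALSE)
  bin <- findInterval(mw, qs, rightmost.closed = FALSE) + 1L
  sel <- with_local_seed(seed, {
    sizes <- tabulate(bin, 4)
    # proportional allocation, largest remainders absorb the rounding
    quota_raw <- target_n * sizes / n
    quota <- floor(quota_raw)
    rem <- target_n - sum(quota)
    if (rem > 0) {
      extra <- order(quota_raw - quota, decreasing = TRUE)
      quota[extra[seq_len(rem)]] <- quota[extra[seq_len(rem)]] + 1
    }
    quota <- pmin(quota, sizes)
    short <- target_n - sum(quota)
    while (short > 0) {   # rare: a bin exhausted by rounding
      room <- which(quota < sizes)
      quota[room[1]] <- quota[room[1]] + 1
      short <- short - 1
    }
    unlist(lapply(1:4, function(b) {
      idx <- which(bin == b)
      if (quota[b] == 0) integer(0) else idx[sample.int(length(idx), quota[b])]
    }))
  })
  out <- majority[sort(sel), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- sprintf(
    "%s | balanced: %d -> %d (MW-quartile stratified, seed %d)",
    attr(majority, "provenance") %||% "", n, target_n, as.integer(seed))
  class(out) <- c("odor_dataset", "data.frame")
  out
}

#' Repeated stratified k-fold assignments
#'
#' Builds `repeats` independent stratified k-fold partitions. Within each
#' repeat the folds are disjoint and cover all indices, and per-fold class
#' counts differ from exact proportionality by at most one.
#'
#' @param labels Character or factor vector of class labels.
#' @param k Number of folds (default 5).
#' @param repeats Number of repetitions (default 10).
#' @param seed Integer seed; each repeat derives its own shuffle.
#' @return A list of length `repeats`; each element is an integer vector in
#'   `1..k` assigning every index to a fold.
#' @export
make_cv_splits <- function(labels, k = 5, repeats = 10, seed = 1) {
  labels <- as.character(labels)
  stopifnot(k >= 2, repeats >= 1)
  counts <- table(labels)
  if (length(counts) < 2) stop2("both classes must be present")
  small <- counts[counts < k]
  if (length(small)) {
    stop2("class '%s' has %d members, fewer than k = %d folds",
          names(small)[1], small[1], k)
  }
  lapply(seq_len(repeats), function(r) {
    fold <- integer(length(labels))
    with_local_seed(derive_seed(seed, paste0("cv-repeat-", r)), {
      for (cl in names(counts)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
    fold
  })
}
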
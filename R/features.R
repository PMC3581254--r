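#' One-hot encoding of amino-acid type
#'
#' Encodes one-letter codes as 20-dimensional binary vectors in the fixed
#' alphabetical order `ACDEFGHIKLMNPQRSTVWY` (see [aa_alphabet()]). The
#' unknown code `'X'` encodes as the all-zero vector; any other unrecognized
#' letter also encodes as all zeros, with a warning.
#'
#' @param aa Character vector of one-letter amino-acid codes.
#' @return Binary matrix with `length(aa)` rows and 20 columns named
#'   `AA_A` ... `AA_Y`.
#' @examples
#' encode_aa(c("A", "Y", "X"))
#' @export
encode_aa <- function(aa) {
  alpha <- aa_alphabet()
  m <- matrix(0, nrow = length(aa), ncol = 20,
              dimnames = list(NULL, paste0("AA_", alpha)))
  pos <- match(aa, alpha)
  unknown <- is.na(pos) & aa != "X"
  if (any(unknown)) {
    warning("unrecognized amino-acid code(s): ",
            paste(unique(aa[unknown]), collapse = ", "),
            " encoded as all-zero")
  }
  ok <- which(!is.na(pos))
  m[cbind(ok, pos[ok])] <- 1
  m
}

#' Parse a PSI-BLAST ASCII PSSM into a conservation track
#'
#' Reads the text PSSM produced by `psiblast -out_ascii_pssm` and extracts the
#' "information per position" column (the second-to-last numeric field of each
#' residue row) as a per-position sequence-conservation score.
#'
#' @param pssm_path Path to the ASCII PSSM file.
#' @return A `conservation_track`: data frame with columns `pos` (sequential
#'   position), `aa` (query letter) and `cons` (information per position,
#'   bits, >= 0).
#' @export
parse_pssm <- function(pssm_path) {
  if (!file.exists(pssm_path)) stop("PSSM file not found: ", pssm_path)
  lines <- readLines(pssm_path, warn = FALSE)
  is_row <- grepl("^\\s*\\d+\\s+[A-Z]\\s", lines)
  if (!any(is_row)) stop("no PSSM residue rows found in ", pssm_path)
  rows <- lapply(which(is_row), function(ln) {
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    # pos, letter, 20 scores, 20 frequencies, information, relative weight
    if (length(tok) < 24L) {
      stop("malformed PSSM row at line ", ln, ": too few fields")
    }
    info <- suppressWarnings(as.numeric(tok[length(tok) - 1L]))
    if (is.na(info)) stop("malformed PSSM row at line ", ln)
    data.frame(pos = as.integer(tok[1]), aa = tok[2], cons = info,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("conservation_track", "data.frame")
  out
}

#' Align a conservation track to a chain
#'
#' PSSM rows carry sequential numbering only, so alignment is positional:
#' row k of the track maps to residue k of the chain. Letter disagreements are
#' tolerated up to 5% of positions (warning); beyond that an error is raised.
#'
#' @param track A `conservation_track` from [parse_pssm()].
#' @param chain A `chain_structure`.
#' @return Numeric vector of conservation scores, one per chain residue (`NA`
#'   where the track is shorter than the chain).
#' @export
align_conservation <- function(track, chain) {
  stopifnot(inherits(chain, "chain_structure"))
  n <- nrow(chain)
  cons <- rep(NA_real_, n)
  k <- min(n, nrow(track))
  cons[seq_len(k)] <- track$cons[seq_len(k)]
  mism <- sum(track$aa[seq_len(k)] != chain$aa[seq_len(k)])
  if (mism / k > 0.05) {
    stop("conservation track disagrees with chain sequence at ", mism,
         " of ", k, " positions (> 5%)")
  }
  if (mism > 0) {
    warning(mism, " letter mismatch(es) between PSSM and chain; values kept")
  }
  cons
}

.FEATURE_SETS <- list(
  "AA" = "AA",
  "SEQ" = "Z_SEQ",
  "STR" = "Z_STR",
  "SEQ+STR" = c("Z_SEQ", "Z_STR"),
  "B" = "Z_B",
  "AA+SEQ" = c("AA", "Z_SEQ"),
  "SEQ+C" = c("Z_SEQ", "CONS")
)

#' Assemble a per-residue feature table
#'
#' Builds the design matrix for SVM training from one or more chains and
#' their flexibility profiles. Each entry of `chains` is a list with elements
#' `chain` (a `chain_structure`), `profile` (its [chain_profile()]) and
#' optionally `cons` (a conservation vector from [align_conservation()]).
#' Rows follow the input chain order and, within a chain, sequence order;
#' rows with any undefined feature are dropped and counted.
#'
#' Named feature sets: `"AA"` (20-bit amino-acid type), `"SEQ"`, `"STR"`,
#' `"SEQ+STR"`, `"B"`, `"AA+SEQ"`, `"SEQ+C"`; or pass a character vector of
#' primitive names from `AA`, `Z_SEQ`, `Z_STR`, `Z_B`, `CONS`.
#'
#' @param chains List of entries as described above.
#' @param feature_set Named combination or character vector of primitives.
#' @return A `feature_table`: list with `X` (numeric matrix), `y` (integer
#'   0/1, 1 = catalytic), `groups` (data frame `pdb_id`, `chain_id`,
#'   `res_seq`, `icode`, `aa`), `feature_names`, and `n_dropped`.
#' @export
build_feature_table <- function(chains, feature_set = "SEQ") {
  if (length(feature_set) == 1L && feature_set %in% names(.FEATURE_SETS)) {
    prims <- .FEATURE_SETS[[feature_set]]
    set_name <- feature_set
  } else {
    prims <- feature_set
    set_name <- paste(feature_set, collapse = "+")
  }
  bad <- setdiff(prims, c("AA", "Z_SEQ", "Z_STR", "Z_B", "CONS"))
  if (length(bad)) stop("unknown feature primitive(s): ", paste(bad, collapse = ", "))
  blocks <- lapply(chains, function(entry) {
    ch <- entry$chain
    pr <- entry$profile
    stopifnot(inherits(ch, "chain_structure"),
              inherits(pr, "flexibility_profile"),
              nrow(ch) == nrow(pr))
    cols <- list()
    for (p in prims) {
      cols[[p]] <- switch(
        p,
        AA = encode_aa(ch$aa),
        Z_SEQ = matrix(pr$z_seq, ncol = 1, dimnames = list(NULL, "Z_SEQ")),
        Z_STR = matrix(pr$z_str, ncol = 1, dimnames = list(NULL, "Z_STR")),
        Z_B = matrix(pr$z_b, ncol = 1, dimnames = list(NULL, "Z_B")),
        CONS = {
          if (is.null(entry$cons)) {
            stop("feature set requires CONS but entry for ",
                 attr(ch, "pdb_id"), " has no conservation track")
          }
          matrix(entry$cons, ncol = 1, dimnames = list(NULL, "CONS"))
        }
      )
    }
    X <- do.call(cbind, cols)
    groups <- data.frame(
      pdb_id = attr(ch, "pdb_id"),
      chain_id = attr(ch, "chain_id"),
      res_seq = ch$res_seq,
      icode = ch$icode,
      aa = ch$aa,
      stringsAsFactors = FALSE
    )
    list(X = X, y = as.integer(ch$is_catalytic), groups = groups)
  })
  X <- do.call(rbind, lapply(blocks, `[[`, "X"))
  y <- unlist(lapply(blocks, `[[`, "y"))
  groups <- do.call(rbind, lapply(blocks, `[[`, "groups"))
  ok <- stats::complete.cases(X)
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    warning(n_dropped, " residue row(s) with undefined features dropped")
  }
  out <- list(
    X = X[ok, , drop = FALSE],
    y = y[ok],
    groups = groups[ok, , drop = FALSE],
    feature_names = colnames(X),
    feature_set = set_name,
    n_dropped = n_dropped
  )
  rownames(out$groups) <- NULL
  class(out) <- "feature_table"
  out
}

#' Subset the rows of a feature table
#'
#' @param table A `feature_table`.
#' @param idx Integer or logical row index.
#' @return A `feature_table` with the selected rows.
#' @export
subset_feature_table <- function(table, idx) {
  stopifnot(inherits(table, "feature_table"))
  out <- table
  out$X <- table$X[idx, , drop = FALSE]
  out$y <- table$y[idx]
  out$groups <- table$groups[idx, , drop = FALSE]
  rownames(out$groups) <- NULL
  out
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d residues x %d features [%s], %d positive, %d proteins\n",
    nrow(x$X), ncol(x$X), x$feature_set, sum(x$y == 1L),
    length(unique(paste(x$groups$pdb_id, x$groups$chain_id)))))
  invisible(x)
}

#' Write a feature table to TSV
#'
#' @param table A `feature_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- cbind(table$groups, as.data.frame(table$X), label = table$y)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path TSV file path.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = list(icode = "character"))
  meta <- c("pdb_id", "chain_id", "res_seq", "icode", "aa", "label")
  feats <- setdiff(names(df), meta)
  df$icode[is.na(df$icode)] <- ""
  out <- list(
    X = as.matrix(df[, feats, drop = FALSE]),
    y = as.integer(df$label),
    groups = df[, c("pdb_id", "chain_id", "res_seq", "icode", "aa")],
    feature_names = feats,
    feature_set = paste(feats, collapse = "+"),
    n_dropped = 0L
  )
  class(out) <- "feature_table"
  out
}
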
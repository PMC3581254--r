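#' @importFrom stats dist
#' @importFrom utils read.table write.table
#' @importFrom bio3d read.pdb write.pdb
#' @importFrom e1071 svm
NULL

# 3-letter -> 1-letter map. MSE (selenomethionine) is retained and mapped to
# its parent M even when deposited as HETATM, the usual crystallographic
# convention; other nonstandard residues are dropped.
.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M"
)

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard one-letter codes in alphabetical order
#' (ACDEFGHIKLMNPQRSTVWY); this ordering fixes the one-hot encoding.
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

new_chain_structure <- function(df, pdb_id, chain_id) {
  df <- df[order(df$res_seq, df$icode), , drop = FALSE]
  rownames(df) <- NULL
  key <- paste(df$res_seq, df$icode)
  if (anyDuplicated(key)) stop("duplicate residues on (res_seq, icode)")
  if (nrow(df) < 2L) {
    stop("chain has fewer than 2 usable residues; profiles are undefined")
  }
  if (!all(is.finite(as.matrix(df[, c("x", "y", "z")])))) {
    stop("non-finite C-alpha coordinates")
  }
  if (any(df$b_factor < 0)) stop("negative B-factors")
  if (!all(df$aa %in% c(aa_alphabet(), "X"))) stop("invalid amino-acid codes")
  attr(df, "pdb_id") <- pdb_id
  attr(df, "chain_id") <- chain_id
  class(df) <- c("chain_structure", "data.frame")
  df
}

#' Read one protein chain from a PDB file
#'
#' Parses a PDB file (via \pkg{bio3d}) and extracts a clean single-chain
#' residue list for flexibility analysis. All heteroatoms, ligands, waters and
#' other nonprotein molecules are removed; only standard amino-acid residues
#' (plus MSE, mapped to M) that have a C-alpha atom are kept. The position of
#' each residue is its C-alpha coordinate and its B-factor is the C-alpha
#' B column. When alternate locations are present, the highest-occupancy
#' altloc is kept (ties go to the first encountered). Residues without a
#' C-alpha atom are dropped with a warning.
#'
#' @param pdb_path Path to a PDB file.
#' @param chain_id Single chain identifier to extract, e.g. `"A"`.
#' @param model_index Model to use for multi-model entries (default 1).
#' @param pdb_id Identifier stored on the result; defaults to the file name
#'   without extension.
#' @return A `chain_structure`: a data frame with columns `chain`, `res_seq`,
#'   `icode`, `aa`, `x`, `y`, `z`, `b_factor`, `is_catalytic` (all `FALSE`
#'   until labels are applied), ordered by (`res_seq`, `icode`), with
#'   attributes `pdb_id` and `chain_id`.
#' @seealso [read_labels()], [apply_labels()], [chain_profile()]
#' @export
read_chain <- function(pdb_path, chain_id, model_index = 1L, pdb_id = NULL) {
  if (!file.exists(pdb_path)) stop("PDB file not found: ", pdb_path)
  if (is.null(pdb_id)) pdb_id <- sub("\\.[^.]*$", "", basename(pdb_path))
  multi <- model_index > 1L
  pdb <- bio3d::read.pdb(pdb_path, multi = multi, rm.alt = FALSE,
                         verbose = FALSE)
  atoms <- pdb$atom
  if (multi) {
    if (model_index > nrow(pdb$xyz)) {
      stop("model ", model_index, " not present (file has ",
           nrow(pdb$xyz), " models)")
    }
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  }
  if (!chain_id %in% atoms$chain) {
    stop("chain '", chain_id, "' not found in ", pdb_path)
  }
  atoms <- atoms[atoms$chain == chain_id, , drop = FALSE]
  # protein residues only: standard ATOM records, plus MSE however deposited
  keep <- (atoms$type == "ATOM" & atoms$resid %in% names(.AA3TO1)) |
    atoms$resid == "MSE"
  atoms <- atoms[keep, , drop = FALSE]
  icode <- ifelse(is.na(atoms$insert), "", atoms$insert)
  res_key <- paste(atoms$resno, icode)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca_icode <- ifelse(is.na(ca$insert), "", ca$insert)
  n_no_ca <- length(setdiff(unique(res_key), paste(ca$resno, ca_icode)))
  if (n_no_ca > 0L) {
    warning(n_no_ca, " residue(s) without a C-alpha atom dropped from ",
            pdb_id, ":", chain_id)
  }
  if (nrow(ca) == 0L) stop("no usable residues in chain ", chain_id)
  # altloc: keep highest occupancy per residue, first encountered on ties
  occ <- ifelse(is.na(ca$o), 1, ca$o)
  ord <- order(ca$resno, ca_icode, -occ)
  ca <- ca[ord, , drop = FALSE]
  ca_icode <- ca_icode[ord]
  first <- !duplicated(paste(ca$resno, ca_icode))
  ca <- ca[first, , drop = FALSE]
  ca_icode <- ca_icode[first]
  df <- data.frame(
    chain = ca$chain,
    res_seq = ca$resno,
    icode = ca_icode,
    aa = unname(.AA3TO1[ca$resid]),
    x = ca$x, y = ca$y, z = ca$z,
    b_factor = ifelse(is.na(ca$b), 0, ca$b),
    is_catalytic = FALSE,
    stringsAsFactors = FALSE
  )
  new_chain_structure(df, pdb_id = pdb_id, chain_id = chain_id)
}

#' Read catalytic-residue labels
#'
#' Reads a set of catalytic-residue keys from either a Catalytic Site Atlas
#' style comma-separated flat file (columns: PDB id, site number, residue
#' type, chain, residue number, ...) or a simple TSV with columns
#' `pdb_id<TAB>chain<TAB>res_seq[<TAB>icode]`. Duplicate keys are collapsed.
#'
#' @param label_path Path to the label file.
#' @param format `"csa_flatfile"` or `"tsv"`.
#' @return A `label_set`: a data frame with columns `pdb_id`, `chain_id`,
#'   `res_seq`, `icode`, one row per distinct catalytic residue.
#' @export
read_labels <- function(label_path, format = c("tsv", "csa_flatfile")) {
  format <- match.arg(format)
  if (!file.exists(label_path)) stop("label file not found: ", label_path)
  lines <- readLines(label_path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (format == "csa_flatfile") {
    sep <- ","
    min_fields <- 5L
    idx <- c(pdb = 1L, chain = 4L, resno = 5L)
  } else {
    sep <- "\t"
    min_fields <- 3L
    idx <- c(pdb = 1L, chain = 2L, resno = 3L)
  }
  recs <- list()
  bad <- integer(0)
  for (ln in lines_keep) {
    f <- trimws(strsplit(lines[ln], sep, fixed = TRUE)[[1]])
    # header line of a CSA dump (or an optional TSV header)
    if (ln == lines_keep[1] && grepl("pdb", tolower(f[1]))) next
    if (length(f) < min_fields || is.na(suppressWarnings(as.integer(f[idx["resno"]])))) {
      bad <- c(bad, ln)
      next
    }
    icode <- if (format == "tsv" && length(f) >= 4L) f[4L] else ""
    recs[[length(recs) + 1L]] <- data.frame(
      pdb_id = toupper(f[idx["pdb"]]),
      chain_id = f[idx["chain"]],
      res_seq = as.integer(f[idx["resno"]]),
      icode = icode,
      stringsAsFactors = FALSE
    )
  }
  if (length(bad)) {
    stop("malformed label rows at line(s): ", paste(bad, collapse = ", "))
  }
  if (!length(recs)) stop("empty label set in ", label_path)
  out <- unique(do.call(rbind, recs))
  rownames(out) <- NULL
  class(out) <- c("label_set", "data.frame")
  out
}

#' Apply catalytic labels to a chain
#'
#' Flags the residues of `chain` named in `labels` as catalytic. Matching is
#' on (pdb_id, chain_id, res_seq, icode); geometry and ordering are untouched.
#' Label keys addressed to this chain that match no residue are reported with
#' a warning and returned in the `unmatched` attribute.
#'
#' @param chain A `chain_structure`.
#' @param labels A `label_set` from [read_labels()], or a data frame with the
#'   same columns.
#' @return The chain with `is_catalytic` updated.
#' @export
apply_labels <- function(chain, labels) {
  stopifnot(inherits(chain, "chain_structure"))
  sel <- toupper(labels$pdb_id) == toupper(attr(chain, "pdb_id")) &
    labels$chain_id == attr(chain, "chain_id")
  lab <- labels[sel, , drop = FALSE]
  key_chain <- paste(chain$res_seq, chain$icode)
  key_lab <- paste(lab$res_seq, lab$icode)
  hit <- key_lab %in% key_chain
  if (any(!hit)) {
    warning(sum(!hit), " label(s) matched no residue in ",
            attr(chain, "pdb_id"), ":", attr(chain, "chain_id"))
  }
  chain$is_catalytic <- key_chain %in% key_lab
  attr(chain, "unmatched") <- lab[!hit, , drop = FALSE]
  chain
}

#' Write a chain as a C-alpha-only PDB file
#'
#' Serializes a `chain_structure` back to PDB format (one CA ATOM record per
#' residue) via \pkg{bio3d}, suitable for round-tripping synthetic chains
#' through [read_chain()].
#'
#' @param chain A `chain_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(chain, path) {
  stopifnot(inherits(chain, "chain_structure"))
  n <- nrow(chain)
  aa3 <- names(.AA3TO1)[match(chain$aa, .AA3TO1)]
  aa3[is.na(aa3)] <- "UNK"
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(chain[, c("x", "y", "z")]))),
    resno = chain$res_seq,
    resid = aa3,
    chain = rep(attr(chain, "chain_id"), n),
    insert = chain$icode,
    elety = rep("CA", n),
    b = chain$b_factor,
    o = rep(1, n)
  )
  invisible(path)
}

#' Write a chain as TSV
#'
#' @param chain A `chain_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chain_tsv <- function(chain, path) {
  stopifnot(inherits(chain, "chain_structure"))
  utils::write.table(as.data.frame(chain), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure> %s:%s, %d residues, %d catalytic\n",
              attr(x, "pdb_id"), attr(x, "chain_id"), nrow(x),
              sum(x$is_catalytic)))
  invisible(x)
}
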
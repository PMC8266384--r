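#' Physicochemical residue classes for conservation scoring
#'
#' Amino acids are grouped so that a substitution within a group still counts
#' as conserved: aromatic (F, W, Y), aliphatic (A, I, L, V), alcohol
#' (S, T), positively charged (R, K), negatively charged (D, E), side-chain
#' amide (N, Q); C, G, H and M each form their own class, as does P (proline
#' shares no listed group and is treated like the other singletons).  Gaps
#' map to a distinguished `"gap"` label and `X` to `"unknown"`; neither ever
#' matches a real class.
#'
#' @param aa character vector of one-letter residue codes (case-insensitive)
#'   or gap characters (`-`, `.`).
#' @return Character vector of class labels.
#' @export
#' @examples
#' residue_class(c("F", "K", "C", "P", "-"))
residue_class <- function(aa) {
  map <- c(F = "aromatic", W = "aromatic", Y = "aromatic",
           A = "aliphatic", I = "aliphatic", L = "aliphatic", V = "aliphatic",
           S = "alcohol", T = "alcohol",
           R = "positive", K = "positive",
           D = "negative", E = "negative",
           N = "amide", Q = "amide",
           C = "cysteine", G = "glycine", H = "histidine",
           M = "methionine", P = "proline",
           X = "unknown", `-` = "gap", `.` = "gap")
  key <- toupper(as.character(aa))
  key[key == "."] <- "-"
  out <- map[key]
  if (anyNA(out))
    stop("unknown residue code(s): ",
         paste(unique(key[is.na(out)]), collapse = ", "))
  unname(out)
}

# Classes that can never constitute a match.
.nonmatching_classes <- c("gap", "unknown")

#' Score one alignment column against a reference residue
#'
#' The score is the fraction of comparator sequences whose residue falls in
#' the same physicochemical class as the reference residue: 1 means every
#' homolog conserves the residue type, 0 means none does.  Gaps and unknown
#' residues count as non-matching but stay in the denominator.
#'
#' @param ref_aa the reference residue (one-letter code; must not be a gap).
#' @param comparators one-letter codes of the other sequences at this column.
#' @return A similarity score in `[0, 1]`.
#' @export
#' @examples
#' column_score("K", c("R", "K", "E", "D", "Q"))  # 0.4
column_score <- function(ref_aa, comparators) {
  if (!length(comparators)) stop("empty comparator set")
  rc <- residue_class(ref_aa)
  if (rc %in% .nonmatching_classes)
    stop("reference residue must not be a gap or unknown")
  cc <- residue_class(comparators)
  mean(cc == rc & !(cc %in% .nonmatching_classes))
}

# Read an aligned FASTA or Clustal file into a named character vector of
# equal-length aligned sequences.  Clustal is parsed directly (name +
# sequence chunk per line, conservation lines and block numbers ignored).
.read_alignment <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^CLUSTAL", first, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)[-1]
    acc <- list()
    for (ln in lines) {
      if (!grepl("^\\S", ln)) next  # blank or conservation line
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(tok) < 2) next
      chunk <- gsub("[0-9]", "", paste(tok[-1], collapse = ""))
      acc[[tok[1]]] <- paste0(acc[[tok[1]]] %||% "", chunk)
    }
    if (!length(acc)) stop("no sequences found in Clustal file ", path)
    return(toupper(unlist(acc)))
  }
  aln <- seqinr::read.alignment(path, format = "fasta",
                                forceToLower = FALSE)
  seqs <- toupper(vapply(aln$seq, paste, character(1), collapse = ""))
  names(seqs) <- aln$nam
  seqs
}

#' Score conservation along a reference sequence in an alignment
#'
#' Each non-gap position of the reference row is scored against all other
#' rows with [column_score()]; results are indexed by the ungapped reference
#' numbering (1-based).  The reference itself is excluded from the
#' comparator set.
#'
#' @param alignment path to an aligned FASTA or Clustal file, or a named
#'   character vector of equal-length aligned sequences.
#' @param reference_id name of the reference row.
#' @param mask optional integer vector of ungapped reference positions to
#'   drop from the output (e.g. to exclude a divergent domain).
#' @return A data frame of class `"conservation_scores"` with columns
#'   `position`, `residue`, `score`.
#' @export
score_alignment <- function(alignment, reference_id, mask = NULL) {
  seqs <- if (is.character(alignment) && length(alignment) == 1 &&
              file.exists(alignment)) .read_alignment(alignment)
          else toupper(alignment)
  if (!reference_id %in% names(seqs))
    stop("reference sequence '", reference_id, "' not found in alignment")
  if (length(unique(nchar(seqs))) != 1)
    stop("ragged alignment: rows differ in length")
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(mat) <- names(seqs)
  ref <- mat[reference_id, ]
  comp <- mat[setdiff(rownames(mat), reference_id), , drop = FALSE]
  if (!nrow(comp)) stop("alignment has no comparator sequences")
  keep <- !(residue_class(ref) %in% "gap")
  pos <- cumsum(keep)
  score <- vapply(which(keep), function(j) column_score(ref[j], comp[, j]),
                  numeric(1))
  out <- data.frame(position = pos[keep], residue = ref[keep], score = score,
                    stringsAsFactors = FALSE)
  if (!is.null(mask)) out <- out[!(out$position %in% mask), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("conservation_scores", "data.frame")
  out
}

#' Write conservation scores into the B-factor field of a structure
#'
#' Every atom of a scored residue in the target chain receives
#' `B = 100 * score` (scaled to preserve two decimals in the fixed-width PDB
#' field); residues of that chain without a score receive the sentinel
#' `-1.00`.  The result is written as a PDB file suitable for surface
#' colouring by B-factor in molecular-graphics tools (red 1 through yellow
#' 0.5 to white 0 in the usual rendering).
#'
#' @param scores a `"conservation_scores"` frame from [score_alignment()].
#' @param structure_path path to the full-atom PDB/mmCIF file to annotate.
#' @param chain chain identifier to map onto.
#' @param offset integer added to the ungapped reference position to obtain
#'   the chain residue number.
#' @param output path of the PDB file to write.
#' @return Invisibly, a data frame of `(resno, score)` actually mapped.
#' @export
map_to_structure <- function(scores, structure_path, chain, offset = 0L,
                             output) {
  stopifnot(is.data.frame(scores), all(scores$score >= 0 & scores$score <= 1))
  ext <- tolower(tools::file_ext(structure_path))
  pdb <- switch(ext,
    pdb = , ent = bio3d::read.pdb(structure_path, verbose = FALSE),
    cif = , mmcif = bio3d::read.cif(structure_path, verbose = FALSE),
    stop("unknown structure format '.", ext, "'"))
  target <- pdb$atom$chain == chain & pdb$atom$type == "ATOM"
  resno <- scores$position + offset
  hit <- match(pdb$atom$resno, resno)
  mapped <- target & !is.na(hit)
  if (!any(mapped))
    stop("mapping error: no scored position lands on chain ", chain)
  pdb$atom$b[target] <- -1
  pdb$atom$b[mapped] <- round(scores$score[hit[mapped]] * 100, 2)
  bio3d::write.pdb(pdb, file = output)
  invisible(data.frame(resno = resno, score = scores$score))
}
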
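#' Read an atomic model as a C-alpha-only structure
#'
#' Parses a PDB or mmCIF file (dispatching on the file extension) and keeps
#' one C-alpha per protein residue.  Alternate locations are resolved to the
#' highest-occupancy conformer (ties broken alphabetically by altloc id);
#' insertion codes are retained as part of the residue label so numbering
#' stays unique.  All distance and superposition operations in this package
#' are C-alpha based.
#'
#' @param path path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @return A data frame of class `"structure_model"` with columns `chain`,
#'   `resno`, `ins`, `resid`, `x`, `y`, `z` and attributes `source`,
#'   `format`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- switch(ext,
    pdb = , ent = bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    cif = , mmcif = bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    stop("unknown structure format '.", ext, "' (expected PDB or mmCIF)"))
  at <- pdb$atom
  ca <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (!nrow(ca)) stop("format error: no C-alpha atoms in ", path)
  if (is.null(ca$insert)) ca$insert <- ""
  ca$insert[is.na(ca$insert)] <- ""
  if (is.null(ca$alt)) ca$alt <- ""
  ca$alt[is.na(ca$alt)] <- ""
  if (is.null(ca$o)) ca$o <- 1
  ca$o[is.na(ca$o)] <- 1
  # altloc: keep the highest-occupancy conformer, ties alphabetical
  key <- paste(ca$chain, ca$resno, ca$insert, sep = "|")
  ord <- order(key, -ca$o, ca$alt)
  ca <- ca[ord, , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno, ca$insert, sep = "|")), ,
           drop = FALSE]
  out <- data.frame(chain = ca$chain, resno = ca$resno, ins = ca$insert,
                    resid = ca$resid, x = ca$x, y = ca$y, z = ca$z,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resno, out$ins), , drop = FALSE]
  rownames(out) <- NULL
  if (!all(is.finite(as.matrix(out[c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  attr(out, "source") <- path
  attr(out, "format") <- if (ext %in% c("pdb", "ent")) "pdb" else "mmcif"
  class(out) <- c("structure_model", "data.frame")
  out
}

#' Download a deposited structure from the PDB archive
#'
#' Convenience fetcher for deposited accessions (requires network access).
#'
#' @param accession 4-character PDB id, e.g. `"7AMK"`.
#' @param destdir directory to save into.
#' @param format `"pdb"` or `"cif"`.
#' @return The downloaded file path.
#' @export
fetch_structure <- function(accession, destdir = tempdir(), format = "pdb") {
  format <- match.arg(format, c("pdb", "cif"))
  dest <- file.path(destdir, paste0(tolower(accession), ".", format))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.%s",
                   toupper(accession), format)
    utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  }
  dest
}

#' Residue range selector
#'
#' @param chain chain identifier.
#' @param start,end first and last residue number (inclusive).
#' @return A list of class `"residue_range"`.
#' @export
residue_range <- function(chain, start, end) {
  stopifnot(start <= end)
  structure(list(chain = as.character(chain), start = start, end = end),
            class = "residue_range")
}

# Resolve one or more residue ranges to a keyed C-alpha coordinate set.
.resolve_ranges <- function(model, ranges) {
  if (inherits(ranges, "residue_range")) ranges <- list(ranges)
  sel <- rep(FALSE, nrow(model))
  for (r in ranges)
    sel <- sel | (model$chain == r$chain & model$resno >= r$start &
                  model$resno <= r$end)
  m <- model[sel, , drop = FALSE]
  list(key = paste0(m$resno, m$ins), resno = m$resno,
       xyz = as.matrix(m[c("x", "y", "z")]))
}

# Kabsch: optimal proper rotation R and translation t minimising
# || Q - (P R^T + t) || over paired rows; returns list(R, t, rmsd).
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cq - as.vector(R %*% cp)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

#' Least-squares rigid superposition of two residue selections
#'
#' Superposes the C-alpha set selected by `moving` onto the set selected by
#' `reference`, pairing residues by residue number (the selections usually
#' address the same domain on two chains of one model).  The optimal proper
#' rotation comes from the SVD construction with determinant correction;
#' residues present in only one selection are dropped with a message.
#'
#' @param model a [read_structure()] model.
#' @param moving,reference a [residue_range()] or list of them.
#' @return A list of class `"superposition"`: `rotation` (3x3, det +1),
#'   `translation` (the transform is `x -> rotation %*% x + translation`),
#'   `rmsd_A`, `n_atoms`.
#' @export
superpose <- function(model, moving, reference) {
  a <- .resolve_ranges(model, moving)
  b <- .resolve_ranges(model, reference)
  common <- intersect(a$key, b$key)
  if (length(common) < 3) {
    miss <- union(setdiff(a$key, b$key), setdiff(b$key, a$key))
    stop("cannot pair residue selections; unmatched residues: ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  dropped <- (length(a$key) - length(common)) + (length(b$key) - length(common))
  if (dropped > 0)
    message(dropped, " unpaired residue(s) dropped from the superposition")
  P <- a$xyz[match(common, a$key), , drop = FALSE]
  Q <- b$xyz[match(common, b$key), , drop = FALSE]
  k <- .kabsch(P, Q)
  structure(list(rotation = k$R, translation = k$t, rmsd_A = k$rmsd,
                 n_atoms = length(common)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition over %d C-alphas: rmsd %.3f A, rotation %.2f deg\n",
              x$n_atoms, x$rmsd_A, rotation_angle(x$rotation)))
  invisible(x)
}

#' Rotation angle of a proper rotation matrix
#'
#' `acos((trace(R) - 1) / 2)` in degrees, with the argument clamped to
#' `[-1, 1]` against round-off.
#'
#' @param rotation a 3x3 proper rotation matrix.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(rotation) {
  if (!is.matrix(rotation) || any(dim(rotation) != 3) ||
      max(abs(rotation %*% t(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("input is not a proper rotation matrix")
  acos(min(1, max(-1, (sum(diag(rotation)) - 1) / 2))) * 180 / pi
}

#' Hinge angle and maximum displacement between two chains of a model
#'
#' Measures interdomain flexing between two copies of a molecule: chain B is
#' first superposed onto chain A over the reference domain, then the residual
#' rotation needed to superpose the (already aligned) chain-B moving domain
#' onto chain A's gives the hinge angle; the maximum displacement is the
#' largest C-alpha shift in the moving domain after the reference alignment.
#' With reference CLD(1-2) and moving CLD(3-4) this reproduces the pivot of
#' the rigid CLD(3-4) module about the CLD(2-3) calcium-binding interface.
#'
#' @param model a [read_structure()] model containing both chains.
#' @param reference_domain,moving_domain residue-number ranges
#'   (`c(start, end)` or a list of such) applied to both chains.
#' @param chain_a,chain_b the fixed and the superposed chain.
#' @return A list of class `"hinge_report"`: `hinge_angle_deg`,
#'   `max_displacement_A`, `at_residue`, `reference_rmsd_A`.
#' @export
hinge <- function(model, reference_domain, moving_domain,
                  chain_a = "A", chain_b = "B") {
  as_ranges <- function(spec, chain) {
    if (is.numeric(spec)) spec <- list(spec)
    lapply(spec, function(r) residue_range(chain, r[1], r[2]))
  }
  ref_a <- as_ranges(reference_domain, chain_a)
  ref_b <- as_ranges(reference_domain, chain_b)
  mov_a <- as_ranges(moving_domain, chain_a)
  mov_b <- as_ranges(moving_domain, chain_b)

  s1 <- superpose(model, ref_b, ref_a)
  bm <- .resolve_ranges(model, mov_b)
  am <- .resolve_ranges(model, mov_a)
  common <- intersect(bm$key, am$key)
  if (length(common) < 3) stop("moving domain cannot be paired across chains")
  B <- bm$xyz[match(common, bm$key), , drop = FALSE]
  A <- am$xyz[match(common, am$key), , drop = FALSE]
  B_aligned <- B %*% t(s1$rotation) +
    matrix(s1$translation, nrow(B), 3, byrow = TRUE)
  k2 <- .kabsch(B_aligned, A)
  disp <- sqrt(rowSums((B_aligned - A)^2))
  imax <- which.max(disp)
  structure(list(hinge_angle_deg = rotation_angle(k2$R),
                 max_displacement_A = unname(disp[imax]),
                 at_residue = unname(am$resno[match(common, am$key)][imax]),
                 reference_rmsd_A = s1$rmsd_A,
                 n_atoms = length(common)),
            class = "hinge_report")
}

#' @export
print.hinge_report <- function(x, ...) {
  cat(sprintf(
    "Hinge: %.2f deg, max displacement %.2f A at residue %d (%d C-alphas, ref rmsd %.2f A)\n",
    x$hinge_angle_deg, x$max_displacement_A, x$at_residue, x$n_atoms,
    x$reference_rmsd_A))
  invisible(x)
}

#' C-alpha to C-alpha distance
#'
#' @param model a [read_structure()] model.
#' @param chain_a,res_a,chain_b,res_b chain ids and residue numbers.
#' @return Euclidean distance in Angstrom.
#' @export
ca_distance <- function(model, chain_a, res_a, chain_b, res_b) {
  pick <- function(chain, res) {
    i <- which(model$chain == chain & model$resno == res)
    if (!length(i))
      stop(sprintf("residue %s/%s has no C-alpha in the model", chain, res))
    as.numeric(model[i[1], c("x", "y", "z")])
  }
  sqrt(sum((pick(chain_a, res_a) - pick(chain_b, res_b))^2))
}

#' Run a batch of named geometric measurements
#'
#' The measurement spec is a list (or a JSON file holding one) of entries
#' with a `name` and a `type`: `"distance"` entries carry `chain_a`,
#' `res_a`, `chain_b`, `res_b`; `"hinge"` entries carry `reference` and
#' `moving` ranges (`[start, end]`) plus `chain_a`/`chain_b`.  Failed
#' lookups are reported per row, not fatally.
#'
#' @param model a [read_structure()] model.
#' @param spec a list of measurement entries or a path to a JSON file.
#' @return A data frame with columns `name`, `type`, `value`, `unit`,
#'   `status`.
#' @export
measure_report <- function(model, spec) {
  if (is.character(spec) && length(spec) == 1)
    spec <- jsonlite::read_json(spec, simplifyVector = FALSE)
  rows <- lapply(spec, function(ms) {
    res <- tryCatch({
      if (ms$type == "distance") {
        list(value = ca_distance(model, ms$chain_a, ms$res_a,
                                 ms$chain_b, ms$res_b),
             unit = "A", status = "ok")
      } else if (ms$type == "hinge") {
        h <- hinge(model, unlist(ms$reference), unlist(ms$moving),
                   ms$chain_a %||% "A", ms$chain_b %||% "B")
        list(value = h$hinge_angle_deg, unit = "deg", status = "ok")
      } else stop("unknown measurement type: ", ms$type)
    }, error = function(e)
      list(value = NA_real_, unit = "", status = conditionMessage(e)))
    data.frame(name = ms$name, type = ms$type, value = res$value,
               unit = res$unit, status = res$status,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), type = character(0), value = numeric(0),
               unit = character(0), status = character(0))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
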
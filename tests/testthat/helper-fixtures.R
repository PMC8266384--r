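# Fixture builders shared across the suite.  Everything is generated in code
# so the repository ships no binary data.

# Random particle table: n particles on n_mic micrographs.
random_table <- function(n, n_mic = 2, field = 2000, pixel_size = 1.26) {
  particle_table(
    micrograph = sample(sprintf("mic_%02d", seq_len(n_mic)), n, replace = TRUE),
    x_px = runif(n, 0, field), y_px = runif(n, 0, field),
    psi_deg = runif(n, -360, 720),
    class_id = sample(1:5, n, replace = TRUE),
    pixel_size_A = pixel_size
  )
}

# Independent all-against-all oracle for find_pairs: O(n^2) enumeration.
brute_force_pairs <- function(table, config) {
  ps <- attr(table, "pixel_size_A")
  if (is.na(ps)) ps <- config$pixel_size_A
  out <- list()
  n <- nrow(table)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (table$micrograph[i] != table$micrograph[j]) next
    d_px <- sqrt((table$x_px[i] - table$x_px[j])^2 +
                 (table$y_px[i] - table$y_px[j])^2)
    if (d_px > config$cutoff_px) next
    out[[length(out) + 1]] <- data.frame(
      micrograph = table$micrograph[i],
      id_a = min(table$particle_id[i], table$particle_id[j]),
      id_b = max(table$particle_id[i], table$particle_id[j]),
      distance_A = d_px * ps,
      dpsi_deg = delta_psi(table$psi_deg[i], table$psi_deg[j],
                           config$symmetry_fold, config$circular_dpsi))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(micrograph = character(0), id_a = integer(0),
               id_b = integer(0), distance_A = numeric(0),
               dpsi_deg = numeric(0))
  res <- res[order(res$micrograph, res$id_a, res$id_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# A flat RELION-style STAR fixture written as text.
write_star_fixture <- function(path, with_psi = TRUE) {
  labels <- c("_rlnMicrographName #1", "_rlnCoordinateX #2",
              "_rlnCoordinateY #3",
              if (with_psi) "_rlnAnglePsi #4",
              "_rlnClassNumber #5", "_rlnSomethingElse #6")
  rows <- c(
    paste("mic_a.mrc 100.500000 200.250000", if (with_psi) "30.000000",
          "1 foo"),
    paste("mic_a.mrc 300.000000 400.000000", if (with_psi) "-15.500000",
          "2 bar"),
    paste("mic_b.mrc  50.000000  60.000000", if (with_psi) "359.990000",
          "1 baz"))
  writeLines(c("data_", "", "loop_", labels, rows), path)
  path
}

# An optics-group (RELION 3.1 style) STAR fixture carrying the pixel size.
write_optics_star_fixture <- function(path, pixel_size = 1.26) {
  writeLines(c(
    "data_optics", "", "loop_",
    "_rlnOpticsGroup #1", "_rlnImagePixelSize #2",
    sprintf("1 %.6f", pixel_size), "",
    "data_particles", "", "loop_",
    "_rlnCoordinateX #1", "_rlnCoordinateY #2", "_rlnAnglePsi #3",
    "_rlnMicrographName #4",
    "10.000000 20.000000 5.000000 mic_a.mrc",
    "700.000000 20.000000 100.000000 mic_a.mrc"), path)
  path
}

# Minimal PDB fixture: one CA per residue from a coordinate matrix.
write_pdb_fixture <- function(path, xyz, chain = "A",
                              resno = seq_len(nrow(xyz)),
                              occ = rep(1, nrow(xyz)),
                              alt = rep("", nrow(xyz)),
                              resid = "ALA", hetatm = FALSE) {
  rec <- if (hetatm) "HETATM" else "ATOM  "
  lines <- sprintf(
    "%s%5d  CA %s%s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    rec, seq_len(nrow(xyz)), alt_field(alt), resid, chain, resno,
    xyz[, 1], xyz[, 2], xyz[, 3], occ, 20)
  writeLines(c(lines, "END"), path)
  path
}
alt_field <- function(alt) ifelse(alt == "", " ", alt)

# The same content as mmCIF (standard RCSB atom_site column order).
write_cif_fixture <- function(path, xyz, chain = "A",
                              resno = seq_len(nrow(xyz)), resid = "ALA") {
  cols <- c("group_PDB", "id", "type_symbol", "label_atom_id",
            "label_alt_id", "label_comp_id", "label_asym_id",
            "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
            "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
            "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
            "auth_comp_id", "auth_asym_id", "auth_atom_id",
            "pdbx_PDB_model_num")
  rows <- sprintf(
    "ATOM %d C CA . %s %s 1 %d ? %.3f %.3f %.3f 1.00 20.00 ? %d %s %s CA 1",
    seq_len(nrow(xyz)), resid, chain, resno, xyz[, 1], xyz[, 2], xyz[, 3],
    resno, resid, chain)
  writeLines(c("data_fixture", "#", "loop_",
               paste0("_atom_site.", cols), rows, "#"), path)
  path
}

# Rotation matrix about an arbitrary axis (degrees).
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# A folded 3D chain used as a generic protein-like point cloud.
helix_coords <- function(n, radius = 5, rise = 1.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq_len(n)
  cbind(radius * cos(t), radius * sin(t), rise * t)
}
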
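#' Particle tables
#'
#' A particle table is the in-memory form of RELION-style per-particle
#' metadata: one row per picked particle with its micrograph label, centroid
#' coordinates in pixels, in-plane rotation angle psi in degrees and an
#' optional 2D-class label.  Coordinates follow RELION picking conventions
#' (pixel-valued, origin at 0); conversion to Angstrom happens downstream via
#' the pixel size.
#'
#' @param micrograph character vector of micrograph labels.
#' @param x_px,y_px particle centroid coordinates in pixels (finite,
#'   non-negative).
#' @param psi_deg in-plane rotation angle in degrees (any finite real).
#' @param class_id optional integer 2D-class label (`NA` allowed).
#' @param pixel_size_A pixel size in Angstrom per pixel, or `NA` if unknown.
#' @param extra optional data frame of additional per-particle columns carried
#'   through I/O untouched.
#'
#' @return A data frame of class `"particle_table"` with columns
#'   `particle_id` (0-based, row order), `micrograph`, `x_px`, `y_px`,
#'   `psi_deg`, `class_id`, plus any extra columns, and attribute
#'   `pixel_size_A`.
#' @export
particle_table <- function(micrograph, x_px, y_px, psi_deg,
                           class_id = NA_integer_, pixel_size_A = NA_real_,
                           extra = NULL) {
  n <- length(x_px)
  stopifnot(length(y_px) == n, length(psi_deg) == n)
  if (!all(is.finite(x_px)) || !all(is.finite(y_px)))
    stop("particle coordinates must be finite")
  if (!all(is.finite(psi_deg)))
    stop("psi angles must be finite")
  if (!is.na(pixel_size_A) && pixel_size_A <= 0)
    stop("pixel_size_A must be positive")
  tab <- data.frame(
    particle_id = seq_len(n) - 1L,
    micrograph  = rep_len(as.character(micrograph), n),
    x_px        = as.numeric(x_px),
    y_px        = as.numeric(y_px),
    psi_deg     = as.numeric(psi_deg),
    class_id    = rep_len(suppressWarnings(as.integer(class_id)), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra) && ncol(extra) > 0) tab <- cbind(tab, extra)
  attr(tab, "pixel_size_A") <- as.numeric(pixel_size_A)
  class(tab) <- c("particle_table", "data.frame")
  tab
}

#' @export
print.particle_table <- function(x, ...) {
  ps <- attr(x, "pixel_size_A")
  cat(sprintf("Particle table: %d particles, %d micrograph(s), pixel size %s\n",
              nrow(x), length(unique(x$micrograph)),
              if (is.na(ps)) "unknown" else sprintf("%.3f A/px", ps)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

# Canonical RELION loop labels for the fields the analysis needs.
.star_default_fields <- c(
  micrograph = "rlnMicrographName",
  x_px       = "rlnCoordinateX",
  y_px       = "rlnCoordinateY",
  psi_deg    = "rlnAnglePsi",
  class_id   = "rlnClassNumber"
)
.star_pixel_labels <- c("rlnImagePixelSize", "rlnDetectorPixelSize")

# Tokenise one STAR data row, honouring single/double quotes.
.star_split_row <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  tok <- regmatches(line, list(m))[[1]]
  gsub("^['\"]|['\"]$", "", tok)
}

# Parse a STAR file into blocks: list(name -> list(loops = list of
# list(labels, rows), pairs = named character of key-value items)).
.star_parse_blocks <- function(lines) {
  lines <- sub("\\s+$", "", lines)
  blocks <- list()
  cur <- NULL
  i <- 1L
  n <- length(lines)
  open_block <- function(name) list(name = name, pairs = character(0),
                                    loops = list())
  while (i <= n) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) { i <- i + 1L; next }
    if (startsWith(ln, "data_")) {
      if (!is.null(cur)) blocks[[cur$name]] <- cur
      cur <- open_block(sub("^data_", "", ln))
      i <- i + 1L
    } else if (ln == "loop_") {
      if (is.null(cur)) cur <- open_block("")
      i <- i + 1L
      labels <- character(0)
      while (i <= n && startsWith(trimws(lines[i]), "_")) {
        labels <- c(labels, sub("^_", "", strsplit(trimws(lines[i]),
                                                   "\\s+")[[1]][1]))
        i <- i + 1L
      }
      rows <- list()
      while (i <= n) {
        rl <- trimws(lines[i])
        if (rl == "" || startsWith(rl, "data_") || rl == "loop_" ||
            startsWith(rl, "_")) break
        if (!startsWith(rl, "#")) {
          tok <- .star_split_row(rl)
          if (length(tok) != length(labels))
            stop(sprintf(
              "STAR parse error at line %d: %d tokens for %d columns",
              i, length(tok), length(labels)))
          rows[[length(rows) + 1L]] <- tok
        }
        i <- i + 1L
      }
      cur$loops[[length(cur$loops) + 1L]] <-
        list(labels = labels,
             rows = if (length(rows)) do.call(rbind, rows) else
               matrix(character(0), 0, length(labels)))
    } else if (startsWith(ln, "_")) {
      if (is.null(cur)) cur <- open_block("")
      tok <- .star_split_row(ln)
      cur$pairs[sub("^_", "", tok[1])] <- if (length(tok) > 1) tok[2] else ""
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!is.null(cur)) blocks[[cur$name]] <- cur
  blocks
}

.star_numeric <- function(x, label) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !(x %in% c("", "NA")))
  if (length(bad))
    stop(sprintf("malformed numeric value '%s' in column %s at data row %d",
                 x[bad[1]], label, bad[1]))
  out
}

#' Read a RELION-dialect STAR particle file
#'
#' Supports both the flat dialect (a single `data_` block holding the particle
#' loop) and the optics-group dialect (`data_optics` + `data_particles`), in
#' which case the pixel size is taken from the optics block when present.
#' Unknown loop columns are preserved and written back out by
#' [write_star()]; row order is preserved.
#'
#' @param path path to a STAR file.
#' @param field_map optional named character vector overriding the default
#'   RELION column labels; names among `micrograph`, `x_px`, `y_px`,
#'   `psi_deg`, `class_id`.
#' @param pixel_size_A pixel size override in Angstrom per pixel; if `NULL`
#'   the value is taken from the file (optics block or a pixel-size column)
#'   when available.
#'
#' @return A [particle_table()].
#' @export
read_star <- function(path, field_map = NULL, pixel_size_A = NULL) {
  if (!file.exists(path)) stop("STAR file not found: ", path)
  fields <- .star_default_fields
  if (!is.null(field_map)) fields[names(field_map)] <- field_map

  blocks <- .star_parse_blocks(readLines(path, warn = FALSE))
  if (!length(blocks)) stop("no data block found in ", path)

  # locate the particle loop: the first loop containing the coordinate columns
  part <- NULL
  for (b in blocks) for (lp in b$loops) {
    if (all(fields[c("x_px", "y_px")] %in% lp$labels)) { part <- lp; break }
  }
  if (is.null(part)) {
    # fall back to the first loop so the missing-column error names columns
    for (b in blocks) if (length(b$loops)) { part <- b$loops[[1]]; break }
    if (is.null(part)) stop("no loop_ block found in ", path)
  }
  for (req in c("x_px", "y_px", "psi_deg")) {
    if (!(fields[[req]] %in% part$labels))
      stop(sprintf("STAR format error: required column _%s missing",
                   fields[[req]]))
  }

  col <- function(lab) part$rows[, match(lab, part$labels)]
  x   <- .star_numeric(col(fields[["x_px"]]), fields[["x_px"]])
  y   <- .star_numeric(col(fields[["y_px"]]), fields[["y_px"]])
  psi <- .star_numeric(col(fields[["psi_deg"]]), fields[["psi_deg"]])
  mic <- if (fields[["micrograph"]] %in% part$labels)
    col(fields[["micrograph"]]) else rep("micrograph_1", length(x))
  cls <- if (fields[["class_id"]] %in% part$labels)
    as.integer(.star_numeric(col(fields[["class_id"]]), fields[["class_id"]]))
  else NA_integer_

  ps <- NA_real_
  if (!is.null(pixel_size_A)) {
    ps <- pixel_size_A
  } else {
    for (lab in .star_pixel_labels) {
      if (lab %in% part$labels) {
        ps <- .star_numeric(col(lab), lab)[1]; break
      }
      for (b in blocks) for (lp in b$loops) {
        if (lab %in% lp$labels && nrow(lp$rows) > 0) {
          ps <- .star_numeric(lp$rows[, match(lab, lp$labels)], lab)[1]
        }
      }
      for (b in blocks) if (lab %in% names(b$pairs))
        ps <- .star_numeric(b$pairs[[lab]], lab)
      if (!is.na(ps)) break
    }
  }

  known <- unname(fields)
  extra_lab <- setdiff(part$labels, c(known, .star_pixel_labels))
  extra <- NULL
  if (length(extra_lab)) {
    extra <- as.data.frame(part$rows[, match(extra_lab, part$labels),
                                     drop = FALSE],
                           stringsAsFactors = FALSE)
    names(extra) <- extra_lab
  }
  particle_table(mic, x, y, psi, cls, pixel_size_A = ps, extra = extra)
}

#' Write a particle table as a flat RELION-dialect STAR file
#'
#' Emits a single `data_particles` block with one `loop_`.  Column order is
#' fixed: micrograph name, coordinate X, coordinate Y, angle psi, class number
#' (if any), image pixel size (if known), then any extra columns in their
#' table order.  Numeric fields are written with 6 decimal places, so a
#' read/write round trip reproduces coordinates and angles to 1e-6.
#'
#' @param table a [particle_table()]; must be non-empty.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_star <- function(table, path) {
  stopifnot(inherits(table, "particle_table"))
  if (nrow(table) == 0) stop("refusing to write an empty particle table")
  num <- function(v) sprintf("%.6f", v)
  cols <- list()
  cols[[.star_default_fields[["micrograph"]]]] <- table$micrograph
  cols[[.star_default_fields[["x_px"]]]] <- num(table$x_px)
  cols[[.star_default_fields[["y_px"]]]] <- num(table$y_px)
  cols[[.star_default_fields[["psi_deg"]]]] <- num(table$psi_deg)
  if (!all(is.na(table$class_id)))
    cols[[.star_default_fields[["class_id"]]]] <-
      as.character(table$class_id)
  ps <- attr(table, "pixel_size_A")
  if (!is.null(ps) && !is.na(ps))
    cols[["rlnImagePixelSize"]] <- num(rep(ps, nrow(table)))
  core <- c("particle_id", "micrograph", "x_px", "y_px", "psi_deg",
            "class_id")
  for (ex in setdiff(names(table), core))
    cols[[ex]] <- as.character(table[[ex]])

  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open ", path, " for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c("", "data_particles", "", "loop_"), con)
  writeLines(sprintf("_%s #%d", names(cols), seq_along(cols)), con)
  mat <- do.call(cbind, cols)
  writeLines(apply(mat, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
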
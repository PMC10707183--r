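# Frame, trajectory and configuration I/O.  The interchange dialect is
# extended XYZ: one record per frame, a quoted Lattice in the comment line
# (row-major box vectors; the z vector carries the Lees-Edwards tilt in x),
# a Properties descriptor, and per-bead columns.  Checkpoints are the same
# dialect at full (%.17g) precision with velocity columns, sufficient for
# bit-exact restarts because the thermostat stream is keyed on the absolute
# step index stored in the header.

# encode the bond list compactly: maximal runs of consecutive-index bonds
# become "a-b"; isolated bonds "i:j"
encode_bonds <- function(bonds) {
  if (nrow(bonds) == 0) return("")
  consec <- bonds[, 2] == bonds[, 1] + 1L
  parts <- character(0)
  i <- 1L
  while (i <= nrow(bonds)) {
    if (consec[i]) {
      j <- i
      while (j < nrow(bonds) && consec[j + 1L] &&
             bonds[j + 1L, 1] == bonds[j, 2]) j <- j + 1L
      parts <- c(parts, sprintf("%d-%d", bonds[i, 1], bonds[j, 2]))
      i <- j + 1L
    } else {
      parts <- c(parts, sprintf("%d:%d", bonds[i, 1], bonds[i, 2]))
      i <- i + 1L
    }
  }
  paste(parts, collapse = ",")
}

decode_bonds <- function(s) {
  if (is.null(s) || !nzchar(s)) return(matrix(integer(), 0, 2))
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  out <- lapply(parts, function(p) {
    if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      cbind(ab[1]:(ab[2] - 1L), (ab[1] + 1L):ab[2])
    } else {
      ij <- as.integer(strsplit(p, ":", fixed = TRUE)[[1]])
      matrix(ij, 1, 2)
    }
  })
  do.call(rbind, out)
}

#' Write a frame as extended XYZ
#'
#' Writes one extended-XYZ record: bead count, a comment line holding the
#' lattice (with Lees-Edwards tilt), the column descriptor, step, strain and
#' the bond list, then one line per bead.  `checkpoint = TRUE` stores
#' positions and velocities at full precision for bit-exact restart;
#' otherwise positions are written at six decimals and velocities omitted.
#'
#' @param frame A `dpd_frame`.
#' @param path Output file path; with `append = TRUE` records concatenate
#'   into a trajectory file.
#' @param checkpoint Full-precision restart record (default FALSE).
#' @param append Append to an existing trajectory file (default FALSE).
#' @return The path, invisibly.
#' @export
write_frame <- function(frame, path, checkpoint = FALSE, append = FALSE) {
  n <- n_beads(frame)
  b <- frame$box
  lattice <- sprintf("%.17g %.17g %.17g %.17g %.17g %.17g %.17g %.17g %.17g",
                     b[1], 0, 0, 0, b[2], 0, frame$tilt, 0, b[3])
  props <- if (checkpoint)
    "species:S:1:pos:R:3:vel:R:3:cargo:I:1" else
    "species:S:1:pos:R:3:cargo:I:1"
  comment <- sprintf('Lattice="%s" Properties=%s step=%.17g strain=%.17g bonds="%s"',
                     lattice, props, frame$step, frame$strain,
                     encode_bonds(frame$bonds))
  fmt <- if (checkpoint) "%.17g" else "%.6f"
  cols <- cbind(frame$species,
                matrix(sprintf(fmt, frame$positions), n, 3))
  if (checkpoint)
    cols <- cbind(cols, matrix(sprintf("%.17g", frame$velocities), n, 3))
  cols <- cbind(cols, as.integer(frame$cargo))
  lines <- c(sprintf("%d", n), comment, apply(cols, 1, paste, collapse = " "))
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  tryCatch(writeLines(lines, con),
           error = function(e) stop("cannot write frame to '", path, "': ",
                                    conditionMessage(e)))
  invisible(path)
}

# parse key=value tokens (values possibly quoted) from an extXYZ comment line
parse_comment <- function(line) {
  out <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|\\S+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  for (k in seq_along(m)) {
    tok <- substr(line, m[k], m[k] + attr(m, "match.length")[k] - 1)
    eq <- regexpr("=", tok, fixed = TRUE)
    key <- substr(tok, 1, eq - 1)
    val <- substr(tok, eq + 1, nchar(tok))
    out[[key]] <- gsub('^"|"$', "", val)
  }
  out
}

read_frame_record <- function(lines, start, path) {
  n <- suppressWarnings(as.integer(lines[start]))
  if (is.na(n))
    stop("malformed record in '", path, "': bead count expected at line ",
         start)
  if (start + 1 + n > length(lines))
    stop("truncated record in '", path, "': expected ", n,
         " bead lines after line ", start + 1)
  kv <- parse_comment(lines[start + 1])
  if (is.null(kv$Lattice))
    stop("malformed box line in '", path, "': missing Lattice")
  lat <- suppressWarnings(as.numeric(strsplit(trimws(kv$Lattice), "\\s+")[[1]]))
  if (length(lat) != 9 || any(is.na(lat)))
    stop("malformed box line in '", path, "': Lattice needs 9 numbers")
  box <- c(lat[1], lat[5], lat[9])
  tilt <- lat[7]
  props <- kv$Properties
  has_vel <- !is.null(props) && grepl("vel:R:3", props, fixed = TRUE)
  body <- lines[(start + 2):(start + 1 + n)]
  toks <- strsplit(trimws(body), "\\s+")
  ncol_expect <- 5L + if (has_vel) 3L else 0L
  len <- lengths(toks)
  if (any(len != ncol_expect))
    stop("truncated record in '", path, "': bead line with ",
         len[which(len != ncol_expect)[1]], " fields, expected ", ncol_expect)
  tm <- matrix(unlist(toks), ncol = ncol_expect, byrow = TRUE)
  species <- tm[, 1]
  unknown <- setdiff(unique(species), DPD_SPECIES)
  if (length(unknown))
    stop("unknown species label in '", path, "': ",
         paste(unknown, collapse = ", "))
  pos <- matrix(as.numeric(tm[, 2:4]), n, 3)
  vel <- if (has_vel) matrix(as.numeric(tm[, 5:7]), n, 3) else NULL
  cargo <- as.integer(tm[, ncol_expect]) != 0L
  fr <- dpd_frame(pos, velocities = vel, species = species, box = box,
                  bonds = decode_bonds(kv$bonds), cargo = cargo, tilt = tilt,
                  step = if (is.null(kv$step)) 0 else as.numeric(kv$step),
                  strain = if (is.null(kv$strain)) 0 else
                    as.numeric(kv$strain),
                  wrap = FALSE)
  list(frame = fr, next_start = start + 2 + n)
}

#' Read a frame (or trajectory) from extended XYZ
#'
#' Parses the dialect written by [write_frame()].  Unknown species labels,
#' malformed box lines and truncated records raise distinct errors.
#'
#' @param path File path.
#' @return A `dpd_frame` (the first record).
#' @export
read_frame <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("truncated record in '", path, "'")
  read_frame_record(lines, 1L, path)$frame
}

#' @rdname read_frame
#' @return `read_trajectory()`: a list of `dpd_frame`s, one per record.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list()
  at <- 1L
  while (at <= length(lines)) {
    if (!nzchar(trimws(lines[at]))) { at <- at + 1L; next }
    rec <- read_frame_record(lines, at, path)
    frames <- c(frames, list(rec$frame))
    at <- rec$next_start
  }
  frames
}

#' Write a trajectory as concatenated extended-XYZ records
#' @param traj A `dpd_traj` or list of frames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  frames <- if (inherits(traj, "dpd_traj")) traj$frames else traj
  first <- TRUE
  for (f in frames) {
    write_frame(f, path, append = !first)
    first <- FALSE
  }
  invisible(path)
}

# configuration schema: every key the pipeline understands, with defaults
config_schema <- function() {
  list(nC = 3, nB = 3, lA = 6, aAS = 26, aCS = 26, aAB = 40, aBS = 45,
       box_x = 10, box_y = 10, box_z = 10, phi = 0.10, steps = 1000,
       seed = 1, shear_rate = 0, report_every = 0, cutoff = 1,
       bin_width = 0.25, kBT = 1, sigma = 3, dt = 0.04)
}

#' Read a flat key-value run configuration
#'
#' Parses `key = value` lines (`#` starts a comment).  Recognised keys:
#' block lengths `nC, nB, lA`; interaction amplitudes `aAS, aCS, aAB, aBS`;
#' box edges `box_x, box_y, box_z` (or `box` for a cube); `phi`, `steps`,
#' `seed`, `shear_rate`, `report_every`, `cutoff`, `bin_width`, `kBT`,
#' `sigma`, `dt`.  Unknown keys are rejected so that typos cannot silently
#' change a run.
#'
#' @param path Config file path.
#' @return Named list with all schema keys filled (defaults where absent).
#' @export
read_config <- function(path) {
  schema <- config_schema()
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- schema
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed config line: '", ln, "' (expected key = value)")
    key <- trimws(kv[1])
    val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (is.na(val)) stop("non-numeric value for config key '", key, "'")
    if (identical(key, "box")) {
      cfg$box_x <- cfg$box_y <- cfg$box_z <- val
    } else if (key %in% names(schema)) {
      cfg[[key]] <- val
    } else {
      stop("unknown config key: '", key, "'")
    }
  }
  cfg
}

#' Write a run configuration
#' @param cfg Named list as returned by [read_config()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(cfg, path) {
  keys <- names(config_schema())
  writeLines(sprintf("%s = %.17g", keys, as.numeric(cfg[keys])), path)
  invisible(path)
}
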
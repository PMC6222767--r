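#' Read and write xyzq system files
#'
#' The xyzq dialect is a plain-text container for one QM region plus one MM
#' point-charge environment:
#' \preformatted{
#'   n_qm n_mm [net_charge] [multiplicity]
#'   free-form comment line
#'   element x y z q group     # n_qm lines, the QM block, group must be 0
#'   label   x y z q group     # n_mm lines, group >= 1 (charge group)
#' }
#' Coordinates are in angstrom and charges in e. In the QM block the `q`
#' column holds the force-field reference charge (`NA` if absent); the MM
#' `label` is informational (e.g. `OW`, `HW`). Several frames may be
#' concatenated in one file.
#'
#' @param path file path.
#' @param frame 1-based frame index for multi-frame files.
#' @return `read_xyzq()`: a list with elements `qm` (a [qm_region()]) and
#'   `mm` (an [mm_charges()]). `read_xyzq_frames()`: a list of such lists.
#' @export
read_xyzq <- function(path, frame = 1L) {
  frames <- read_xyzq_frames(path)
  if (frame < 1L || frame > length(frames)) {
    rlang::abort(sprintf("frame %d requested but file has %d frame(s)",
                         frame, length(frames)),
                 class = "qmmbed_parse_error")
  }
  frames[[frame]]
}

#' @rdname read_xyzq
#' @export
read_xyzq_frames <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "qmmbed_parse_error")
  }
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frames[[length(frames) + 1L]] <- .parse_xyzq_frame(lines, i, path)
    i <- attr(frames[[length(frames)]], "next_line")
    attr(frames[[length(frames)]], "next_line") <- NULL
  }
  if (!length(frames)) {
    rlang::abort(paste0("no frames found in ", path),
                 class = "qmmbed_parse_error")
  }
  frames
}

.parse_xyzq_frame <- function(lines, start, path) {
  header <- strsplit(trimws(lines[start]), "\\s+")[[1]]
  counts <- suppressWarnings(as.numeric(header))
  if (length(counts) < 2L || anyNA(counts[1:2])) {
    rlang::abort(sprintf("%s line %d: expected header 'n_qm n_mm ...'",
                         path, start), class = "qmmbed_parse_error")
  }
  n_qm <- as.integer(counts[1]); n_mm <- as.integer(counts[2])
  net <- if (length(counts) >= 3L && !is.na(counts[3])) as.integer(counts[3]) else 0L
  mult <- if (length(counts) >= 4L && !is.na(counts[4])) as.integer(counts[4]) else 1L
  body_start <- start + 2L # skip comment line
  last <- body_start + n_qm + n_mm - 1L
  if (last > length(lines)) {
    rlang::abort(sprintf("%s line %d: frame declares %d atoms but file ends",
                         path, start, n_qm + n_mm),
                 class = "qmmbed_parse_error")
  }
  parse_row <- function(k, need_group) {
    f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(f) < 5L) {
      rlang::abort(sprintf(
        "%s line %d: expected 'element x y z q group', got %d field(s) %s",
        path, k, length(f),
        if (length(f) == 4L) "(missing charge column?)" else ""),
        class = "qmmbed_parse_error")
    }
    num <- suppressWarnings(as.numeric(f[2:5]))
    if (anyNA(num)) {
      rlang::abort(sprintf("%s line %d: non-numeric coordinate or charge",
                           path, k), class = "qmmbed_parse_error")
    }
    grp <- if (length(f) >= 6L) suppressWarnings(as.integer(f[6])) else NA_integer_
    if (need_group && is.na(grp)) {
      rlang::abort(sprintf("%s line %d: MM charge lacks a group label",
                           path, k), class = "qmmbed_parse_error")
    }
    list(label = f[1], x = num[1], y = num[2], z = num[3], q = num[4],
         group = grp)
  }
  qm_rows <- lapply(seq_len(n_qm) + body_start - 1L, parse_row,
                    need_group = FALSE)
  mm_rows <- lapply(seq_len(n_mm) + body_start + n_qm - 1L, parse_row,
                    need_group = TRUE)
  g <- function(rows, f) vapply(rows, `[[`, numeric(1), f)
  qref <- if (n_qm) g(qm_rows, "q") else numeric(0)
  qm <- qm_region(
    elements = vapply(qm_rows, `[[`, character(1), "label"),
    coords = cbind(g(qm_rows, "x"), g(qm_rows, "y"), g(qm_rows, "z")),
    q_ref = if (all(is.na(qref)) && n_qm) NULL else qref,
    net_charge = net, multiplicity = mult
  )
  mm <- mm_charges(
    coords = cbind(g(mm_rows, "x"), g(mm_rows, "y"), g(mm_rows, "z")),
    q = if (n_mm) g(mm_rows, "q") else numeric(0),
    group = if (n_mm) vapply(mm_rows, `[[`, integer(1), "group") else integer(0)
  )
  attr(mm, "labels") <- vapply(mm_rows, `[[`, character(1), "label")
  .check_no_overlap(qm, mm)
  out <- list(qm = qm, mm = mm)
  attr(out, "next_line") <- last + 1L
  out
}

.check_no_overlap <- function(qm, mm) {
  if (nrow(mm) == 0L || nrow(qm) == 0L) return(invisible())
  if (any(.min_dist_to_qm(mm, qm) < 1e-6)) {
    rlang::abort("an MM charge coincides with a QM atom (same atom in both regions?)",
                 class = "qmmbed_validation_error")
  }
  invisible()
}

#' @rdname read_xyzq
#' @param qm a [qm_region()].
#' @param mm an [mm_charges()].
#' @param comment comment line written into the frame.
#' @param append append a frame instead of overwriting.
#' @export
write_xyzq <- function(qm, mm, path, comment = "written by qmmbed",
                       append = FALSE) {
  labels <- attr(mm, "labels")
  if (is.null(labels)) labels <- rep("X", nrow(mm))
  fmt <- function(el, x, y, z, q, grp) {
    sprintf("%-4s %18.10f %18.10f %18.10f %14.10f %6d", el, x, y, z, q, grp)
  }
  qref <- ifelse(is.na(qm$q_ref), 0, qm$q_ref)
  out <- c(
    sprintf("%d %d %d %d", nrow(qm), nrow(mm),
            attr(qm, "net_charge"), attr(qm, "multiplicity")),
    comment,
    fmt(qm$element, qm$x, qm$y, qm$z, qref, rep(0L, nrow(qm))),
    if (nrow(mm)) fmt(labels, mm$x, mm$y, mm$z, mm$q, mm$group)
  )
  if (append) cat(out, file = path, sep = "\n", append = TRUE)
  else writeLines(out, path)
  invisible(path)
}

#' Load a system from PDB plus a companion charge table
#'
#' Standard PDB columns provide names, residues and coordinates; partial
#' charges come from a two-column whitespace/comma-separated table
#' (atom serial, charge in e). One residue maps to one charge group, so
#' group-based cutoffs act on whole residues/waters; each monoatomic ion is
#' its own residue and hence its own group. QM membership is selected by
#' residue name.
#'
#' @param pdb_path PDB file path.
#' @param charge_path charge table path (columns: serial, charge).
#' @param qm_resid residue name(s) forming the QM region.
#' @param net_charge,multiplicity passed to [qm_region()].
#' @return list with `qm` and `mm` as for [read_xyzq()].
#' @export
read_pdb_system <- function(pdb_path, charge_path, qm_resid,
                            net_charge = 0L, multiplicity = 1L) {
  rlang::check_installed("bio3d")
  pdb <- bio3d::read.pdb(pdb_path)
  at <- tibble::as_tibble(pdb$atom)
  chg <- utils::read.table(charge_path, header = FALSE,
                           col.names = c("serial", "charge"))
  idx <- match(at$eleno, chg$serial)
  if (anyNA(idx)) {
    rlang::abort(sprintf("charge table is missing %d atom serial(s)",
                         sum(is.na(idx))), class = "qmmbed_parse_error")
  }
  at$q <- chg$charge[idx]
  is_qm <- at$resid %in% qm_resid
  if (!any(is_qm)) {
    rlang::abort(paste0("no atoms with residue name(s): ",
                        paste(qm_resid, collapse = ", ")),
                 class = "qmmbed_validation_error")
  }
  qm_at <- at[is_qm, ]
  mm_at <- at[!is_qm, ]
  elem <- function(d) {
    e <- trimws(d$elesy)
    miss <- !nzchar(e) | is.na(e)
    e[miss] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", d$elety[miss])
    paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, 10)))
  }
  qm <- qm_region(elem(qm_at), cbind(qm_at$x, qm_at$y, qm_at$z),
                  q_ref = qm_at$q, net_charge = net_charge,
                  multiplicity = multiplicity)
  grp <- as.integer(factor(paste(mm_at$chain, mm_at$resno, mm_at$insert)))
  mm <- mm_charges(cbind(mm_at$x, mm_at$y, mm_at$z), mm_at$q, grp)
  attr(mm, "labels") <- elem(mm_at)
  .check_no_overlap(qm, mm)
  list(qm = qm, mm = mm)
}

#' Read a run configuration (YAML or JSON)
#'
#' Recognised keys mirror the command-line interface: `model`,
#' `switching: {scheme, r_off, r_on}`, `cutoff: {mode}`, `backend`,
#' `grid: {shells, density}`, `tddft: {n_states}`. Missing keys take package
#' defaults.
#'
#' @param path config file (`.yaml`/`.yml`/`.json`).
#' @return a named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("config not found: ", path),
                 class = "qmmbed_parse_error")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- list(
    model = "espcd",
    switching = list(scheme = "lrec", r_off = 10, r_on = NULL),
    cutoff = list(mode = "atom"),
    backend = "surrogate",
    grid = list(shells = c(1.4, 1.6, 1.8, 2.0), density = 1.0),
    tddft = list(n_states = 1L)
  )
  utils::modifyList(defaults, cfg)
}
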
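# Reflection sets: the tabular container every structure-factor score
# consumes. A reflection set is a tibble of merged Miller-indexed intensity
# records plus the unit cell that defines their resolutions.

#' Construct a reflection set
#'
#' Bundles a unit cell with a table of background-subtracted Bragg
#' intensities. Resolutions are always recomputed from the cell and Miller
#' indices, never taken from a file column, so every downstream statistic
#' shares one resolution convention. Friedel mates are folded onto one
#' hemisphere and duplicate (h,k,l) records are merged by
#' inverse-variance-weighted averaging, so anomalous pairs contribute a
#' single record.
#'
#' @param records A data frame with integer columns `h`, `k`, `l`, intensity
#'   `I` (may be negative: weak background-subtracted data) and uncertainty
#'   `sigI` (must be strictly positive).
#' @param cell A [unit_cell()].
#' @param source_label Free-text provenance tag.
#' @param flags Character vector of QC flags to carry (e.g.
#'   "amplitudes-squared").
#' @return A `reflection_set`: a tibble with columns h, k, l, I, sigI, d, s
#'   and attributes `cell`, `source_label`, `flags`.
#' @export
reflection_set <- function(records, cell, source_label = "unknown",
                           flags = character()) {
  stopifnot(inherits(cell, "unit_cell"))
  records <- tibble::as_tibble(records)
  need <- c("h", "k", "l", "I", "sigI")
  if (!all(need %in% names(records))) {
    stop("records must have columns h, k, l, I, sigI", call. = FALSE)
  }
  bad <- which(!is.finite(records$sigI) | records$sigI <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive sigma in record(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  if (any(records$h == 0 & records$k == 0 & records$l == 0)) {
    stop("records contain the (0,0,0) reflection", call. = FALSE)
  }

  # Fold Friedel mates onto one hemisphere: flip by the sign of the first
  # nonzero index.
  h <- records$h; k <- records$k; l <- records$l
  sgn <- sign(h)
  sgn[h == 0] <- sign(k)[h == 0]
  sgn[h == 0 & k == 0] <- sign(l)[h == 0 & k == 0]
  records$h <- h * sgn; records$k <- k * sgn; records$l <- l * sgn

  # Merge duplicates with inverse-variance weights (skipped when all
  # triplets are already unique).
  off <- 2 * max(abs(c(records$h, records$k, records$l))) + 1
  key <- (records$h * off + records$k) * off + records$l
  if (anyDuplicated(key)) {
    records <- dplyr::group_by(records, .data$h, .data$k, .data$l)
    records <- dplyr::summarise(
      records,
      I = sum(.data$I / .data$sigI^2) / sum(1 / .data$sigI^2),
      sigI = 1 / sqrt(sum(1 / .data$sigI^2)),
      .groups = "drop"
    )
  } else {
    records <- records[, c("h", "k", "l", "I", "sigI")]
  }

  records$d <- d_spacing(cell, as.matrix(records[, c("h", "k", "l")]))
  records$s <- 1 / records$d
  records <- records[order(-records$d, records$h, records$k, records$l), ]
  structure(records,
            class = c("reflection_set", class(records)),
            cell = cell, source_label = source_label, flags = flags)
}

#' @export
print.reflection_set <- function(x, ...) {
  cell <- attr(x, "cell")
  cat(sprintf("<reflection_set> %d reflections, d %.2f-%.2f A [%s]\n",
              nrow(x), max(x$d), min(x$d), attr(x, "source_label")))
  if (length(attr(x, "flags"))) {
    cat("flags:", paste(attr(x, "flags"), collapse = ", "), "\n")
  }
  NextMethod()
}

#' Read reflection data into a reflection set
#'
#' Supports three dialects: a plain whitespace table (`h k l I sigI` with a
#' `# cell a b c alpha beta gamma` header comment), structure-factor mmCIF
#' (`_refln` loop; intensity columns preferred, amplitude columns squared
#' with first-order error propagation and a carried "amplitudes-squared"
#' flag), and MTZ (converted through the external `gemmi` Python module,
#' which must be importable by `python` on the PATH).
#'
#' @param path Input file.
#' @param format_hint One of "table", "sf-cif", "mtz"; guessed from the file
#'   extension when omitted.
#' @param cell Optional [unit_cell()] overriding (or supplying, for headerless
#'   tables) the cell.
#' @return A [reflection_set()].
#' @export
read_reflections <- function(path, format_hint = NULL, cell = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- format_hint %||% switch(tolower(tools::file_ext(path)),
    "cif" = "sf-cif", "ent" = "sf-cif", "mtz" = "mtz", "table")
  switch(fmt,
    "table"  = read_reflection_table(path, cell),
    "sf-cif" = read_reflection_cif(path, cell),
    "mtz"    = read_reflection_mtz(path, cell),
    stop("unknown format_hint: ", fmt, call. = FALSE)
  )
}

read_reflection_table <- function(path, cell = NULL) {
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#\\s*cell\\b", lines, value = TRUE, ignore.case = TRUE)
  if (is.null(cell)) {
    if (!length(header)) {
      stop("missing unit cell: no '# cell' header and no cell supplied",
           call. = FALSE)
    }
    v <- as.numeric(strsplit(trimws(sub("^#\\s*cell", "", header[1],
                                        ignore.case = TRUE)), "\\s+")[[1]])
    if (length(v) != 6 || any(!is.finite(v))) {
      stop("malformed '# cell' header", call. = FALSE)
    }
    cell <- unit_cell(v[1], v[2], v[3], v[4], v[5], v[6])
  }
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(body)) stop("no reflection records in ", path, call. = FALSE)
  rec <- utils::read.table(text = body)
  if (ncol(rec) < 5) {
    stop("table needs five columns: h k l I sigI", call. = FALSE)
  }
  names(rec)[1:5] <- c("h", "k", "l", "I", "sigI")
  reflection_set(rec[, 1:5], cell, source_label = basename(path))
}

#' Write a reflection set in the plain table dialect
#'
#' @param refl A [reflection_set()].
#' @param path Output path.
#' @param digits Decimal digits written for I and sigI.
#' @return `path`, invisibly.
#' @export
write_reflections <- function(refl, path, digits = 6) {
  cell <- attr(refl, "cell")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cell %.6f %.6f %.6f %.4f %.4f %.4f",
                     cell$a, cell$b, cell$c,
                     cell$alpha, cell$beta, cell$gamma), con)
  writeLines(sprintf("%d %d %d %.*f %.*f", refl$h, refl$k, refl$l,
                     digits, refl$I, digits, refl$sigI), con)
  invisible(path)
}

# Minimal structure-factor mmCIF reader: cell items + one _refln loop.
read_reflection_cif <- function(path, cell = NULL) {
  lines <- readLines(path, warn = FALSE)
  item <- function(name) {
    hit <- grep(paste0("^\\s*", name, "\\s"), lines, value = TRUE)
    if (!length(hit)) return(NA_real_)
    as.numeric(strsplit(trimws(hit[1]), "\\s+")[[1]][2])
  }
  if (is.null(cell)) {
    v <- c(item("_cell\\.length_a"), item("_cell\\.length_b"),
           item("_cell\\.length_c"), item("_cell\\.angle_alpha"),
           item("_cell\\.angle_beta"), item("_cell\\.angle_gamma"))
    if (any(is.na(v))) {
      stop("missing unit cell: no _cell items and no cell supplied",
           call. = FALSE)
    }
    cell <- unit_cell(v[1], v[2], v[3], v[4], v[5], v[6])
  }
  loops <- grep("^\\s*loop_", lines)
  refln_loop <- NULL
  for (lp in loops) {
    i <- lp + 1
    tags <- character()
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1
    }
    if (any(grepl("^_refln\\.", tags))) {
      j <- i
      while (j <= length(lines) && !grepl("^\\s*(loop_|_|#|$)", lines[j])) {
        j <- j + 1
      }
      refln_loop <- list(tags = tags, body = lines[i:(j - 1)])
      break
    }
  }
  if (is.null(refln_loop)) stop("no _refln loop in ", path, call. = FALSE)
  tab <- utils::read.table(text = refln_loop$body, na.strings = c("?", "."))
  names(tab) <- refln_loop$tags[seq_len(ncol(tab))]
  col <- function(nm) tab[[nm]]
  h <- col("_refln.index_h"); k <- col("_refln.index_k")
  l <- col("_refln.index_l")
  if (is.null(h)) stop("no Miller index columns in _refln loop", call. = FALSE)
  flags <- character()
  if (!is.null(tab[["_refln.intensity_meas"]])) {
    I <- col("_refln.intensity_meas")
    sigI <- col("_refln.intensity_sigma")
  } else if (!is.null(tab[["_refln.F_meas_au"]]) ||
             !is.null(tab[["_refln.F_meas"]])) {
    Fm <- col("_refln.F_meas_au") %||% col("_refln.F_meas")
    sigF <- col("_refln.F_meas_sigma_au") %||% col("_refln.F_meas_sigma")
    I <- Fm^2
    sigI <- 2 * abs(Fm) * sigF  # first-order propagation of F -> F^2
    flags <- "amplitudes-squared"
  } else {
    stop("no intensity or amplitude column in _refln loop", call. = FALSE)
  }
  ok <- stats::complete.cases(h, k, l, I, sigI)
  reflection_set(data.frame(h = h, k = k, l = l, I = I, sigI = sigI)[ok, ],
                 cell, source_label = basename(path), flags = flags)
}

# MTZ is a binary format; delegate parsing to the gemmi Python module and
# re-read through the table dialect.
read_reflection_mtz <- function(path, cell = NULL) {
  py <- Sys.which("python")
  if (!nzchar(py)) stop("MTZ support needs 'python' with gemmi on the PATH",
                        call. = FALSE)
  tmp <- tempfile(fileext = ".txt")
  code <- sprintf(paste0(
    "import gemmi, sys\n",
    "m = gemmi.read_mtz_file(%s)\n",
    "cols = {c.label: m.column_with_label(c.label) for c in m.columns}\n",
    "def pick(*names):\n",
    "    for n in names:\n",
    "        if n in cols: return cols[n]\n",
    "    return None\n",
    "I, S = pick('IMEAN','I'), pick('SIGIMEAN','SIGI')\n",
    "amp = False\n",
    "if I is None:\n",
    "    I, S = pick('F','FP'), pick('SIGF','SIGFP'); amp = True\n",
    "if I is None: sys.exit('no intensity or amplitude column')\n",
    "H, K, L = cols['H'], cols['K'], cols['L']\n",
    "with open(%s, 'w') as out:\n",
    "    u = m.cell\n",
    "    out.write('# cell %%f %%f %%f %%f %%f %%f\\n' %% ",
    "(u.a, u.b, u.c, u.alpha, u.beta, u.gamma))\n",
    "    if amp: out.write('# amplitudes\\n')\n",
    "    for i in range(len(I)):\n",
    "        out.write('%%d %%d %%d %%g %%g\\n' %% ",
    "(H[i], K[i], L[i], I[i], S[i]))\n"),
    deparse(path), deparse(tmp))
  status <- system2(py, "-", input = code, stdout = TRUE, stderr = TRUE)
  if (!file.exists(tmp)) {
    stop("gemmi MTZ conversion failed: ", paste(status, collapse = " "),
         call. = FALSE)
  }
  refl <- read_reflection_table(tmp, cell)
  if (any(grepl("^# amplitudes", readLines(tmp, n = 2)))) {
    Fm <- refl$I; sigF <- refl$sigI
    refl$I <- Fm^2
    refl$sigI <- pmax(2 * abs(Fm) * sigF, .Machine$double.eps)
    attr(refl, "flags") <- union(attr(refl, "flags"), "amplitudes-squared")
  }
  attr(refl, "source_label") <- basename(path)
  refl
}

`%||%` <- function(a, b) if (is.null(a)) b else a
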
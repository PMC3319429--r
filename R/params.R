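# Nearest-neighbor energy parameter set.
#
# All energies are integers in units of 10 cal/mol ("dekacal") at 37 C.
# Pair types: 1 CG, 2 GC, 3 GU, 4 UG, 5 AU, 6 UA, 7 nonstandard (NN).
# Nucleotide table index is code + 1, so slot 1 is the "no nucleotide"
# column (written E in parameter files) and slots 2..5 are A, C, G, U.

INF_ENERGY <- 10000000

# pair type lookup: 5x5 over nt codes 0..4 (row/col index = code + 1)
.PAIR_TYPE <- local({
  m <- matrix(0L, 5, 5)
  set <- function(a, b, t) m[a + 1L, b + 1L] <<- as.integer(t)
  # A=1 C=2 G=3 U=4
  set(2, 3, 1)  # CG
  set(3, 2, 2)  # GC
  set(3, 4, 3)  # GU
  set(4, 3, 4)  # UG
  set(1, 4, 5)  # AU
  set(4, 1, 6)  # UA
  m
})

# reversed pair type (pair seen from the other strand side)
.RTYPE <- c(2L, 1L, 4L, 3L, 6L, 5L, 7L)

pair_type <- function(a, b) .PAIR_TYPE[a + 1L, b + 1L]

.PAIR_NAMES <- c("CG", "GC", "GU", "UG", "AU", "UA", "NN")

# gas constant times temperature at 37 C, in dekacal units:
# RT = 1.98717e-3 kcal/(mol K) * 310.15 K = 0.61632 kcal/mol = 61.632 dekacal
RT_DEKACAL <- 1.98717e-3 * 310.15 * 100

.PAR_TABLE_SPECS <- list(
  stack                 = c(7, 7),
  mismatch_hairpin      = c(7, 5, 5),
  mismatch_interior     = c(7, 5, 5),
  mismatch_interior_1n  = c(7, 5, 5),
  mismatch_interior_23  = c(7, 5, 5),
  mismatch_multi        = c(7, 5, 5),
  mismatch_exterior     = c(7, 5, 5),
  dangle5               = c(7, 5),
  dangle3               = c(7, 5),
  int11                 = c(7, 7, 5, 5),
  int21                 = c(7, 7, 5, 5, 5),
  int22                 = c(6, 6, 4, 4, 4, 4),
  hairpin               = 31,
  bulge                 = 31,
  interior              = 31
)

# section names as they appear in parameter files (v2.0 dialect)
.PAR_SECTION_ALIASES <- c(
  stack                = "stack",
  mismatch_hairpin     = "mismatch_hairpin",
  mismatch_internal    = "mismatch_interior",
  mismatch_internal_1n = "mismatch_interior_1n",
  mismatch_internal_23 = "mismatch_interior_23",
  mismatch_multi       = "mismatch_multi",
  mismatch_exterior    = "mismatch_exterior",
  dangle5              = "dangle5",
  dangle3              = "dangle3",
  int11                = "int11",
  int21                = "int21",
  int22                = "int22",
  hairpin              = "hairpin",
  bulge                = "bulge",
  internal             = "interior",
  ML_params            = "ML_params",
  NINIO                = "NINIO",
  Misc                 = "Misc",
  Hexaloops            = "Hexaloops",
  Tetraloops           = "Tetraloops",
  Triloops             = "Triloops",
  lxc                  = "lxc"
)

#' Read a nearest-neighbor energy parameter file
#'
#' Parses the human-readable parameter-file dialect: sections introduced by
#' `# name` lines, whitespace-separated integer tables with the keyword `INF`
#' for forbidden entries, and `/* ... */` comments (which may span lines).
#' The table layout follows the structure of the Turner 2004 compilation:
#' `stack`, the mismatch tables, `dangle5`/`dangle3`, the special interior
#' tables `int11`/`int21`/`int22`, the loop-length tables `hairpin`, `bulge`
#' and `internal`, `ML_params`, `NINIO`, `Misc`, and the special hairpin
#' lists `Triloops`/`Tetraloops`/`Hexaloops`.  Sections whose name ends in
#' `_enthalpies` (used only for folding at non-default temperatures) are
#' skipped.  An optional one-number `lxc` section overrides the coefficient
#' of the logarithmic loop-length extrapolation (default 107.856).
#'
#' Missing sections fall back to the corresponding table of `base`, which
#' defaults to an all-zero skeleton (with `INF` in the impossible length
#' slots), so partial files can be used as overlays.
#'
#' @param file Path, connection, or character vector of lines.
#' @param base Optional `energy_params` supplying defaults for absent
#'   sections.
#' @return An object of class `energy_params`.
#' @export
read_energy_params <- function(file, base = NULL) {
  lines <- if (is.character(file) && length(file) == 1L && file.exists(file))
    readLines(file, warn = FALSE)
  else if (inherits(file, "connection")) readLines(file, warn = FALSE)
  else as.character(file)
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("/\\*.*?\\*/", " ", txt, perl = TRUE)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]

  params <- if (is.null(base)) empty_energy_params() else base
  sec <- NULL
  buf <- list()
  flush_section <- function(params) {
    if (is.null(sec) || is.na(sec)) return(params)
    toks <- unlist(buf, use.names = FALSE)
    .assign_param_section(params, sec, toks)
  }
  for (line in lines) {
    if (grepl("^##", line)) next
    if (grepl("^#", line)) {
      params <- flush_section(params)
      raw <- trimws(sub("^#", "", line))
      if (identical(raw, "END")) { sec <- NULL; buf <- list(); next }
      if (grepl("_enthalpies$", raw)) { sec <- NA_character_; buf <- list(); next }
      if (!raw %in% names(.PAR_SECTION_ALIASES)) {
        sec <- NULL; buf <- list()
        stop(sprintf("unknown parameter section '%s'", raw))
      }
      sec <- .PAR_SECTION_ALIASES[[raw]]
      buf <- list()
    } else if (!is.null(sec) && !is.na(sec)) {
      stripped <- trimws(line)
      if (nzchar(stripped)) buf[[length(buf) + 1L]] <- strsplit(stripped, "\\s+")[[1L]]
    }
  }
  params <- flush_section(params)
  params <- .complete_params(params)
  params
}

# all-zero parameter skeleton (INF where a loop size is impossible)
empty_energy_params <- function() {
  mk <- function(dims) array(0, dim = dims)
  p <- list(
    stack = mk(c(7, 7)),
    mismatch_hairpin = mk(c(7, 5, 5)),
    mismatch_interior = mk(c(7, 5, 5)),
    mismatch_interior_1n = mk(c(7, 5, 5)),
    mismatch_interior_23 = mk(c(7, 5, 5)),
    mismatch_multi = mk(c(7, 5, 5)),
    mismatch_exterior = mk(c(7, 5, 5)),
    dangle5 = mk(c(7, 5)),
    dangle3 = mk(c(7, 5)),
    int11 = mk(c(7, 7, 5, 5)),
    int21 = mk(c(7, 7, 5, 5, 5)),
    int22 = mk(c(7, 7, 5, 5, 5, 5)),
    hairpin = c(rep(INF_ENERGY, 3), rep(0, 28)),
    bulge = c(INF_ENERGY, rep(0, 30)),
    interior = c(rep(INF_ENERGY, 2), rep(0, 29)),
    ml_base = 0, ml_closing = 0, ml_intern = 0,
    ninio = 0, max_ninio = 0,
    duplex_init = 0, terminal_au = 0,
    lxc = 107.856,
    triloops = data.frame(seq = character(), energy = numeric()),
    tetraloops = data.frame(seq = character(), energy = numeric()),
    hexaloops = data.frame(seq = character(), energy = numeric())
  )
  class(p) <- "energy_params"
  p
}

.tok_to_num <- function(toks, section) {
  vals <- suppressWarnings(ifelse(toks == "INF", INF_ENERGY, as.numeric(toks)))
  if (anyNA(vals))
    stop(sprintf("non-numeric entry '%s' in section '%s'",
                 toks[which(is.na(vals))[1L]], section))
  vals
}

.assign_param_section <- function(params, sec, toks) {
  if (sec %in% c("Triloops", "Tetraloops", "Hexaloops")) {
    field <- c(Triloops = "triloops", Tetraloops = "tetraloops",
               Hexaloops = "hexaloops")[[sec]]
    if (length(toks) == 0L) {
      params[[field]] <- data.frame(seq = character(), energy = numeric())
      return(params)
    }
    if (length(toks) %% 3L == 0L) per <- 3L
    else if (length(toks) %% 2L == 0L) per <- 2L
    else stop(sprintf("section '%s': expected (sequence, energy[, enthalpy]) rows", sec))
    m <- matrix(toks, ncol = per, byrow = TRUE)
    params[[field]] <- data.frame(seq = m[, 1L],
                                  energy = .tok_to_num(m[, 2L], sec))
    return(params)
  }
  vals <- .tok_to_num(toks, sec)
  if (sec == "ML_params") {
    if (length(vals) %in% c(3L, 6L)) {
      if (length(vals) == 6L) vals <- vals[c(1L, 3L, 5L)]  # drop enthalpies
      params$ml_base <- vals[[1L]]; params$ml_closing <- vals[[2L]]
      params$ml_intern <- vals[[3L]]
    } else stop("section 'ML_params': expected 3 or 6 entries")
    return(params)
  }
  if (sec == "NINIO") {
    if (length(vals) == 3L) { params$ninio <- vals[[1L]]; params$max_ninio <- vals[[3L]] }
    else if (length(vals) == 2L) { params$ninio <- vals[[1L]]; params$max_ninio <- vals[[2L]] }
    else stop("section 'NINIO': expected 2 or 3 entries")
    return(params)
  }
  if (sec == "Misc") {
    if (length(vals) == 4L) { params$duplex_init <- vals[[1L]]; params$terminal_au <- vals[[3L]] }
    else if (length(vals) == 2L) { params$duplex_init <- vals[[1L]]; params$terminal_au <- vals[[2L]] }
    else stop("section 'Misc': expected 2 or 4 entries")
    return(params)
  }
  if (sec == "lxc") {
    if (length(vals) != 1L) stop("section 'lxc': expected 1 entry")
    params$lxc <- vals[[1L]]
    return(params)
  }
  spec <- .PAR_TABLE_SPECS[[sec]]
  expected <- prod(spec)
  if (length(vals) != expected)
    stop(sprintf("section '%s': expected %d entries, got %d", sec, expected, length(vals)))
  if (sec %in% c("hairpin", "bulge", "interior")) {
    params[[sec]] <- vals
    return(params)
  }
  # tables are written with the last index fastest; fill accordingly
  arr <- array(vals, dim = rev(spec))
  arr <- aperm(arr, rev(seq_along(spec)))
  if (sec == "int22") {
    # file stores canonical pairs x ACGU only; embed into the full table,
    # the nonstandard completions are filled in .complete_params()
    full <- array(NA_real_, dim = c(7, 7, 5, 5, 5, 5))
    full[1:6, 1:6, 2:5, 2:5, 2:5, 2:5] <- arr
    params$int22 <- full
  } else {
    params[[sec]] <- arr
  }
  params
}

# Fill derived entries: nonstandard-pair/unknown-nucleotide slots of int22
# take the least stabilizing (maximum) value over canonical completions.
.complete_params <- function(params) {
  if (anyNA(params$int22)) {
    arr <- params$int22
    core <- arr[1:6, 1:6, 2:5, 2:5, 2:5, 2:5, drop = FALSE]
    mx <- max(core)
    # unknown nucleotide slots: max over that nucleotide within same pairs
    filled <- array(mx, dim = dim(arr))
    filled[1:6, 1:6, 2:5, 2:5, 2:5, 2:5] <- core
    # nonstandard pair rows: max over canonical pairs with same nucleotides
    for (p1 in 1:6) for (p2 in 1:6) {
      sub <- core[p1, p2, , , , , drop = FALSE]
      filled[p1, p2, 1, , , ] <- max(sub)
      filled[p1, p2, , 1, , ] <- max(sub)
      filled[p1, p2, , , 1, ] <- max(sub)
      filled[p1, p2, , , , 1] <- max(sub)
      filled[p1, p2, 2:5, 2:5, 2:5, 2:5] <- core[p1, p2, , , , ]
    }
    filled[7, , , , , ] <- mx
    filled[, 7, , , , ] <- mx
    params$int22 <- filled
  }
  params
}

#' Write an energy parameter set to the parameter-file dialect
#'
#' Emits every table in the same section layout accepted by
#' [read_energy_params()], so that load -> dump -> load reproduces the
#' tables exactly.  Enthalpy sections are not part of the model and are not
#' written.
#'
#' @param params An `energy_params` object.
#' @param file Path or connection; if missing, the text is returned.
#' @return The file content as a character vector (invisibly when written).
#' @export
write_energy_params <- function(params, file = NULL) {
  stopifnot(inherits(params, "energy_params"))
  fmt <- function(v) ifelse(v >= INF_ENERGY, "INF", format(v, scientific = FALSE, trim = TRUE))
  emit_table <- function(name, arr) {
    spec <- dim(arr)
    if (is.null(spec)) spec <- length(arr)
    v <- if (length(spec) > 1L) as.vector(aperm(arr, rev(seq_along(spec)))) else arr
    rows <- split(fmt(v), ceiling(seq_along(v) / 10))
    c(paste0("# ", name), vapply(rows, paste, "", collapse = " "))
  }
  out <- c("## loopfold parameter file (Turner 2004 table layout)")
  inv_alias <- names(.PAR_SECTION_ALIASES)
  names(inv_alias) <- .PAR_SECTION_ALIASES
  for (sec in names(.PAR_TABLE_SPECS)) {
    arr <- params[[sec]]
    if (sec == "int22") arr <- arr[1:6, 1:6, 2:5, 2:5, 2:5, 2:5, drop = FALSE]
    out <- c(out, emit_table(inv_alias[[sec]], arr), "")
  }
  out <- c(out,
           "# ML_params",
           paste(fmt(c(params$ml_base, params$ml_closing, params$ml_intern)), collapse = " "),
           "",
           "# NINIO",
           paste(fmt(c(params$ninio, params$max_ninio)), collapse = " "),
           "",
           "# Misc",
           paste(fmt(c(params$duplex_init, params$terminal_au)), collapse = " "),
           "",
           "# lxc",
           format(params$lxc, scientific = FALSE, trim = TRUE),
           "")
  for (fld in c("triloops", "tetraloops", "hexaloops")) {
    name <- c(triloops = "Triloops", tetraloops = "Tetraloops",
              hexaloops = "Hexaloops")[[fld]]
    tab <- params[[fld]]
    out <- c(out, paste0("# ", name))
    if (nrow(tab) > 0L)
      out <- c(out, paste(tab$seq, fmt(tab$energy)))
    out <- c(out, "")
  }
  out <- c(out, "#END")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' The bundled default parameter set (Turner 2004 table structure)
#'
#' Loads the complete default nearest-neighbor set shipped with the package
#' (free energies at 37 C; the special interior tables are stored in
#' separate overlay files purely to keep individual files small).  The
#' result is cached for the session.
#'
#' @return An `energy_params` object.
#' @export
default_energy_params <- function() {
  cached <- .loopfold_cache$default_params
  if (!is.null(cached)) return(cached)
  files <- c("rna_turner2004_core.par",
             "rna_turner2004_int21.par",
             "rna_turner2004_int22.par")
  paths <- vapply(files, function(f)
    system.file("extdata", f, package = "loopfold", mustWork = TRUE), "")
  p <- NULL
  for (path in paths) p <- read_energy_params(path, base = p)
  .loopfold_cache$default_params <- p
  p
}

.loopfold_cache <- new.env(parent = emptyenv())

#' Construct a small hand-auditable parameter set
#'
#' A deliberately simple set used for worked examples and exact tests: one
#' stacking energy shared by all canonical pair combinations, flat loop-length
#' tables, simple affine multiloop coefficients, and (by default) no
#' mismatch, dangle, or special-loop terms, so loop sums can be checked by
#' hand.
#'
#' @param stack Stacking energy (dekacal, default -330).
#' @param hairpin Hairpin length penalty for all sizes >= 3 (default 540).
#' @param bulge Bulge penalty for all sizes >= 1 (default 380).
#' @param interior Interior-loop penalty for sizes >= 2 (default 200).
#' @param int11,int21,int22 Flat special interior-loop values.
#' @param ml_closing,ml_intern,ml_base Affine multiloop coefficients
#'   (default 340, 40, 0).
#' @param ninio,max_ninio Interior-loop asymmetry slope and cap (60, 300).
#' @param terminal_au Penalty per AU/GU helix end (default 50).
#' @param dangle5,dangle3 Flat dangle energies (default 0).
#' @param mismatch Flat value for all mismatch tables (default 0).
#' @param duplex_init Duplex initiation penalty (default 410).
#' @return An `energy_params` object.
#' @export
toy_energy_params <- function(stack = -330, hairpin = 540, bulge = 380,
                              interior = 200, int11 = 40, int21 = 110,
                              int22 = 120, ml_closing = 340, ml_intern = 40,
                              ml_base = 0, ninio = 60, max_ninio = 300,
                              terminal_au = 50, dangle5 = 0, dangle3 = 0,
                              mismatch = 0, duplex_init = 410) {
  p <- empty_energy_params()
  p$stack[1:6, 1:6] <- stack
  p$stack[7, 1:6] <- apply(p$stack[1:6, 1:6, drop = FALSE], 2, max)
  p$stack[1:6, 7] <- apply(p$stack[1:6, 1:6, drop = FALSE], 1, max)
  p$stack[7, 7] <- max(p$stack[1:6, 1:6])
  p$hairpin <- c(rep(INF_ENERGY, 3), rep(hairpin, 28))
  p$bulge <- c(INF_ENERGY, rep(bulge, 30))
  p$interior <- c(rep(INF_ENERGY, 2), rep(interior, 29))
  p$int11[] <- int11
  p$int21[] <- int21
  p$int22[] <- int22
  for (fld in c("mismatch_hairpin", "mismatch_interior", "mismatch_interior_1n",
                "mismatch_interior_23", "mismatch_multi", "mismatch_exterior"))
    p[[fld]][] <- mismatch
  p$dangle5[] <- dangle5
  p$dangle3[] <- dangle3
  p$ml_base <- ml_base; p$ml_closing <- ml_closing; p$ml_intern <- ml_intern
  p$ninio <- ninio; p$max_ninio <- max_ninio
  p$terminal_au <- terminal_au
  p$duplex_init <- duplex_init
  p
}

#' @export
print.energy_params <- function(x, ...) {
  cat("<energy_params>  (dekacal = 10 cal/mol, 37 C)\n")
  cat(sprintf("  stack[CG,CG] = %g, hairpin[3] = %g, bulge[1] = %g\n",
              x$stack[1, 1], x$hairpin[4], x$bulge[2]))
  cat(sprintf("  multiloop a=%g b=%g c=%g; ninio %g (cap %g); terminal AU %g\n",
              x$ml_closing, x$ml_intern, x$ml_base, x$ninio, x$max_ninio,
              x$terminal_au))
  cat(sprintf("  special hairpins: %d tri, %d tetra, %d hexa; lxc = %g\n",
              nrow(x$triloops), nrow(x$tetraloops), nrow(x$hexaloops), x$lxc))
  invisible(x)
}
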
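# Nucleotide integer codes used throughout the package: A=1, C=2, G=3, U=4.
# N (and any IUPAC ambiguity code) is normalized to N and encoded as 0; it
# never forms a base pair.  Tables indexed by nucleotide use code + 1 so that
# slot 1 holds the "no/ambiguous nucleotide" entry.

.NT_LEVELS <- c("A", "C", "G", "U")

#' Create a validated RNA sequence
#'
#' Normalizes an input string to the package's RNA alphabet: lowercase is
#' folded to uppercase, `T` is mapped to `U`, and any IUPAC ambiguity code is
#' mapped to `N`.  `N` positions never pair.  Normalization is idempotent.
#'
#' @param x A single character string of nucleotides.
#' @param name Optional identifier (e.g. from a FASTA header).
#' @return An object of class `rna_sequence`: the normalized string with
#'   attributes `name` and `codes` (integer codes, A=1, C=2, G=3, U=4, N=0).
#' @examples
#' rna_sequence("acgt")   # "ACGU"
#' @export
rna_sequence <- function(x, name = NULL) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("sequence must be a single character string")
  s <- toupper(x)
  s <- chartr("T", "U", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (length(chars) < 1L)
    stop("sequence must have length >= 1")
  ambiguous <- !(chars %in% c(.NT_LEVELS, "N"))
  if (any(ambiguous)) {
    iupac <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
    bad <- which(ambiguous & !(chars %in% iupac))
    if (length(bad) > 0L)
      stop(sprintf("illegal character '%s' at position %d", chars[bad[1L]], bad[1L]))
    chars[ambiguous] <- "N"
  }
  codes <- match(chars, .NT_LEVELS)
  codes[is.na(codes)] <- 0L
  out <- paste(chars, collapse = "")
  structure(out, name = name, codes = as.integer(codes), class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  nm <- attr(x, "name")
  if (!is.null(nm)) cat(">", nm, "\n", sep = "")
  cat(unclass(x), "\n", sep = "")
  invisible(x)
}

# Integer codes of a sequence-like object (rna_sequence or plain string).
seq_codes <- function(seq) {
  if (inherits(seq, "rna_sequence")) return(attr(seq, "codes"))
  attr(rna_sequence(as.character(seq)), "codes")
}

as_rna_sequence <- function(seq) {
  if (inherits(seq, "rna_sequence")) seq else rna_sequence(as.character(seq))
}

.STRUCT_CHARS <- c("(", ")", ".", "x", "|", "<", ">", "&")

#' Read sequence records from FASTA or bare-line input
#'
#' Accepts classic FASTA (`>`-headed, bodies wrapped over any number of
#' lines) and bare single-line records, freely mixed.  A line immediately
#' following a sequence that consists only of structure/constraint characters
#' (`(`, `)`, `.`, `x`, `|`, `<`, `>`, `&`) is attached to the record as its
#' `structure` element, mirroring the sequence-then-structure convention of
#' stream-oriented folding tools.  A `&` inside a sequence splits it into the
#' two strands of a dimer record.
#'
#' @param input A connection, a file path, or a character vector of lines.
#' @return A list of records; each record is a list with elements `seq`
#'   (an [rna_sequence] or, for dimers, a list of two), `structure`
#'   (string or `NULL`) and `name` (string or `NULL`).
#' @export
read_rna_input <- function(input) {
  lines <- if (is.character(input) && length(input) == 1L &&
               !grepl("[\n>]", input) && file.exists(input)) {
    readLines(input, warn = FALSE)
  } else if (inherits(input, "connection")) {
    readLines(input, warn = FALSE)
  } else {
    unlist(strsplit(paste(input, collapse = "\n"), "\n", fixed = TRUE))
  }
  records <- list()
  i <- 1L
  n <- length(lines)
  is_struct_line <- function(x) {
    x <- gsub("\\s", "", x)
    nzchar(x) && all(strsplit(x, "")[[1L]] %in% .STRUCT_CHARS)
  }
  make_record <- function(seq_text, name, lineno) {
    seq_text <- gsub("\\s", "", seq_text)
    if (!nzchar(seq_text))
      stop(sprintf("empty record at line %d", lineno))
    if (grepl("&", seq_text, fixed = TRUE)) {
      parts <- strsplit(seq_text, "&", fixed = TRUE)[[1L]]
      if (length(parts) != 2L || !all(nzchar(parts)))
        stop(sprintf("malformed dimer record at line %d", lineno))
      list(seq = lapply(parts, rna_sequence, name = name),
           structure = NULL, name = name)
    } else {
      list(seq = rna_sequence(seq_text, name = name),
           structure = NULL, name = name)
    }
  }
  while (i <= n) {
    line <- lines[[i]]
    if (!nzchar(gsub("\\s", "", line))) { i <- i + 1L; next }
    if (startsWith(line, ">")) {
      name <- sub("^>\\s*", "", line)
      start <- i + 1L
      body <- character()
      j <- start
      while (j <= n && !startsWith(lines[[j]], ">")) {
        if (is_struct_line(lines[[j]])) break
        if (nzchar(gsub("\\s", "", lines[[j]]))) body <- c(body, lines[[j]])
        j <- j + 1L
      }
      if (length(body) == 0L)
        stop(sprintf("empty record at line %d", i))
      rec <- make_record(paste(body, collapse = ""), name, i)
      if (j <= n && !startsWith(lines[[j]], ">") && is_struct_line(lines[[j]])) {
        rec$structure <- gsub("\\s", "", lines[[j]])
        j <- j + 1L
      }
      records[[length(records) + 1L]] <- rec
      i <- j
    } else {
      rec <- make_record(line, NULL, i)
      i <- i + 1L
      if (i <= n && is_struct_line(lines[[i]]) && !startsWith(lines[[i]], ">")) {
        rec$structure <- gsub("\\s", "", lines[[i]])
        i <- i + 1L
      }
      records[[length(records) + 1L]] <- rec
    }
  }
  records
}

#' Convert dot-bracket notation to a pair table
#'
#' The pair table is the package's canonical structure encoding: an integer
#' vector `p` of length `n` with `p[i] = j` when `(i, j)` is a base pair and
#' `p[i] = 0` when position `i` is unpaired.  Dot-bracket text uses `(`, `)`
#' and `.`; balanced brackets uniquely determine a pseudoknot-free structure.
#'
#' @param text Dot-bracket string (characters `(`, `)`, `.`).
#' @param check_span If `TRUE` (default), reject hairpins enclosing fewer
#'   than three unpaired bases (pairs must satisfy `j - i > 3`).
#' @return Integer pair table of class `pair_table`.
#' @export
parse_dot_bracket <- function(text, check_span = TRUE) {
  chars <- strsplit(as.character(text), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 1L) stop("empty structure string")
  bad <- which(!(chars %in% c("(", ")", ".")))
  if (length(bad) > 0L)
    stop(sprintf("illegal structure character '%s' at position %d",
                 chars[bad[1L]], bad[1L]))
  pt <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    ch <- chars[[i]]
    if (ch == "(") {
      stack <- c(stack, i)
    } else if (ch == ")") {
      if (length(stack) == 0L)
        stop(sprintf("unbalanced structure: unmatched ')' at position %d", i))
      j <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (check_span && i - j <= 3L)
        stop(sprintf("hairpin span violation: pair (%d,%d) encloses fewer than 3 bases", j, i))
      pt[[j]] <- i
      pt[[i]] <- j
    }
  }
  if (length(stack) > 0L)
    stop(sprintf("unbalanced structure: unmatched '(' at position %d",
                 stack[[length(stack)]]))
  structure(pt, class = "pair_table")
}

#' Convert a pair table back to dot-bracket notation
#'
#' Inverse of [parse_dot_bracket()]: `parse_dot_bracket(write_dot_bracket(p))`
#' recovers `p` for every valid pair table.
#'
#' @param pt Integer pair table (`pt[i] = j` for pair `(i, j)`, else 0).
#' @return Dot-bracket string.
#' @export
write_dot_bracket <- function(pt) {
  pt <- as.integer(pt)
  n <- length(pt)
  chars <- rep(".", n)
  for (i in seq_len(n)) {
    j <- pt[[i]]
    if (j > i) { chars[[i]] <- "("; chars[[j]] <- ")" }
  }
  paste(chars, collapse = "")
}

#' Validate a pair table
#'
#' Checks the defining conditions of a pseudoknot-free secondary structure:
#' pairing is symmetric and a matching (no base has two partners), every pair
#' spans at least three unpaired bases, and no two pairs cross.
#'
#' @param pt Integer pair table.
#' @param min_span Minimum `j - i - 1` (default 3 unpaired bases).
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_pair_table <- function(pt, min_span = 3L) {
  pt <- as.integer(pt)
  n <- length(pt)
  for (i in seq_len(n)) {
    j <- pt[[i]]
    if (j < 0L || j > n) stop(sprintf("partner of %d out of range", i))
    if (j != 0L) {
      if (pt[[j]] != i) stop(sprintf("asymmetric pairing at (%d,%d)", i, j))
      if (j == i) stop(sprintf("self pairing at %d", i))
      if (abs(j - i) <= min_span)
        stop(sprintf("hairpin span violation at pair (%d,%d)", min(i, j), max(i, j)))
    }
  }
  # non-crossing: scan with a stack
  stack <- integer(0)
  for (i in seq_len(n)) {
    j <- pt[[i]]
    if (j > i) stack <- c(stack, j)
    else if (j != 0L && j < i) {
      if (length(stack) == 0L || stack[[length(stack)]] != i)
        stop(sprintf("crossing pairs involving (%d,%d)", j, i))
      stack <- stack[-length(stack)]
    }
  }
  invisible(TRUE)
}

#' Parse a folding-constraint string
#'
#' Per-position hard constraints: `.` unconstrained, `x` forced unpaired,
#' `|` forced paired (partner unspecified), and matched `(` `)` forcing the
#' specific pair between the matched positions.  `<` and `>` are accepted as
#' synonyms of `|` restricted to downstream/upstream pairing direction; they
#' are treated as forced paired.
#'
#' @param text Constraint string, same length as the sequence it constrains.
#' @param n Expected length (optional check).
#' @return A list of class `fold_constraints` with elements `unpaired`
#'   (logical), `paired` (logical), and `partner` (integer, 0 when free).
#' @export
parse_constraints <- function(text, n = NULL) {
  chars <- strsplit(as.character(text), "", fixed = TRUE)[[1L]]
  m <- length(chars)
  if (!is.null(n) && m != n)
    stop(sprintf("constraint string length %d does not match sequence length %d", m, n))
  ok <- chars %in% c(".", "x", "|", "(", ")", "<", ">")
  if (!all(ok))
    stop(sprintf("illegal constraint character '%s' at position %d",
                 chars[which(!ok)[1L]], which(!ok)[1L]))
  partner <- integer(m)
  stack <- integer(0)
  for (i in seq_len(m)) {
    if (chars[[i]] == "(") stack <- c(stack, i)
    else if (chars[[i]] == ")") {
      if (length(stack) == 0L)
        stop(sprintf("unbalanced constraint bracket at position %d", i))
      j <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      partner[[i]] <- j
      partner[[j]] <- i
    }
  }
  if (length(stack) > 0L)
    stop(sprintf("unbalanced constraint bracket at position %d",
                 stack[[length(stack)]]))
  structure(list(
    unpaired = chars == "x",
    paired   = chars %in% c("|", "<", ">", "(", ")"),
    partner  = partner
  ), class = "fold_constraints")
}

# Format an energy in the package's output convention: two decimals,
# sign-padded, in kcal/mol, e.g. " -3.40".
format_energy <- function(e_kcal) {
  sprintf("%6.2f", e_kcal)
}
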
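#' Discrete morphological character matrices
#'
#' A `char_matrix` holds a taxa-by-characters table of discrete states.
#' Each cell is a set of non-negative integer states: a singleton for a
#' certain scoring, several states for a polymorphic scoring, or the empty
#' set where the character is missing or inapplicable (the two are not
#' distinguished: neither permits a comparison). Every character carries an
#' ordering flag; differences between states of an ordered character count
#' the steps between them, unordered characters score 0/1.
#'
#' @param states character matrix (taxa in rows, with rownames) in which
#'   each cell is `""` (missing/inapplicable), a single integer such as
#'   `"2"`, or several integers joined by `/` such as `"0/1"` (polymorphism).
#' @param ordering character vector, one of `"ordered"`/`"unordered"` per
#'   character; defaults to all unordered.
#' @return an object of class `char_matrix` with elements `taxa`, `states`,
#'   `ordering` and `n_char`.
#' @examples
#' m <- character_matrix(
#'   rbind(A = c("0", "1", ""), B = c("1", "1", "0")),
#'   ordering = c("unordered", "unordered", "unordered")
#' )
#' completeness(m)
#' @export
character_matrix <- function(states, ordering = NULL) {
  if (!is.matrix(states) || !is.character(states))
    stop("`states` must be a character matrix")
  if (is.null(rownames(states)))
    stop("`states` must have taxon rownames")
  n_char <- ncol(states)
  if (is.null(ordering)) ordering <- rep("unordered", n_char)
  obj <- structure(
    list(taxa = rownames(states), states = states,
         ordering = ordering, n_char = n_char),
    class = "char_matrix"
  )
  validate_char_matrix(obj)
  obj
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("Discrete character matrix:", length(x$taxa), "taxa x",
      x$n_char, "characters\n")
  cat("  ordered characters:", sum(x$ordering == "ordered"), "\n")
  cpl <- completeness(x)
  cat(sprintf("  completeness: %.1f%% to %.1f%% (median %.1f%%)\n",
              100 * min(cpl), 100 * max(cpl), 100 * stats::median(cpl)))
  invisible(x)
}

validate_char_matrix <- function(x) {
  if (anyDuplicated(x$taxa))
    stop("duplicate taxon labels: ",
         paste(unique(x$taxa[duplicated(x$taxa)]), collapse = ", "))
  if (length(x$ordering) != x$n_char)
    stop("ordering flag must be defined for every character")
  if (!all(x$ordering %in% c("ordered", "unordered")))
    stop("ordering flags must be 'ordered' or 'unordered'")
  cells <- x$states[x$states != ""]
  ints <- unlist(strsplit(cells, "/", fixed = TRUE))
  if (length(ints) && (anyNA(suppressWarnings(as.integer(ints))) ||
                       any(as.integer(ints) < 0)))
    stop("states must be non-negative integers")
  empty_char <- colSums(x$states != "") == 0
  if (any(empty_char))
    stop("character(s) with no coded cell: ",
         paste(which(empty_char), collapse = ", "))
  invisible(x)
}

## decode one column of the state table into a list of integer vectors
.cell_sets <- function(column) {
  out <- strsplit(column, "/", fixed = TRUE)
  lapply(out, function(s) if (length(s) == 1L && s == "") integer(0)
         else sort(as.integer(s)))
}

#' Per-taxon completeness
#'
#' The fraction of characters coded (non-empty state set) for each taxon.
#'
#' @param matrix a [character_matrix()].
#' @return named numeric vector of fractions in `[0, 1]`.
#' @export
completeness <- function(matrix) {
  stopifnot(inherits(matrix, "char_matrix"))
  out <- rowSums(matrix$states != "") / matrix$n_char
  names(out) <- matrix$taxa
  out
}

#' Read a NEXUS discrete character matrix
#'
#' Parses the CHARACTERS (or DATA) block of a NEXUS file: symbols are mapped
#' to consecutive integers, `?` (missing) and `-` (inapplicable) both yield
#' the empty state set, and polymorphisms written `(01)` or `{01}` yield
#' multi-state sets. If an ASSUMPTIONS block declares character types
#' (`TYPESET`/`DEFTYPE` with `ord`/`unord` groups), ordering flags are set
#' accordingly; otherwise all characters are unordered.
#'
#' @param path path to a NEXUS file.
#' @return a [character_matrix()].
#' @export
read_nexus_matrix <- function(path) {
  raw <- readLines(path, warn = FALSE)
  lines <- .strip_nexus_comments(raw)
  low <- tolower(lines)
  if (!any(grepl("#nexus", low)))
    stop("parse error at line 1: file does not start with #NEXUS")

  begin <- grep("begin\\s+(characters|data)\\s*;", low)
  if (!length(begin))
    stop("parse error: no CHARACTERS or DATA block found")
  begin <- begin[1]
  ends <- grep("^\\s*end\\s*;", low)
  end <- ends[ends > begin][1]
  if (is.na(end))
    stop(sprintf("parse error at line %d: block opened here lacks END;",
                 begin))
  block <- lines[(begin + 1):(end - 1)]
  block_start <- begin + 1

  ## FORMAT line: symbols, missing, gap
  symbols <- as.character(0:9)
  missing_ch <- "?"; gap_ch <- "-"
  fmt <- grep("^\\s*format\\b", tolower(block))
  if (length(fmt)) {
    f <- block[fmt[1]]
    sym <- regmatches(f, regexpr('symbols\\s*=\\s*"[^"]*"', f, ignore.case = TRUE))
    if (length(sym)) {
      s <- sub('.*"([^"]*)".*', "\\1", sym)
      symbols <- strsplit(gsub("\\s", "", s), "")[[1]]
    }
    mis <- regmatches(f, regexpr("missing\\s*=\\s*\\S", f, ignore.case = TRUE))
    if (length(mis)) missing_ch <- substring(mis, nchar(mis))
    gp <- regmatches(f, regexpr("gap\\s*=\\s*\\S", f, ignore.case = TRUE))
    if (length(gp)) gap_ch <- substring(gp, nchar(gp))
  }

  dim_ln <- grep("^\\s*dimensions\\b", tolower(block))
  n_char_decl <- NA_integer_
  if (length(dim_ln)) {
    d <- block[dim_ln[1]]
    nc <- regmatches(d, regexpr("nchar\\s*=\\s*[0-9]+", d, ignore.case = TRUE))
    if (length(nc)) n_char_decl <- as.integer(sub(".*=\\s*", "", nc))
  }

  mat_ln <- grep("^\\s*matrix\\b", tolower(block))
  if (!length(mat_ln))
    stop(sprintf("parse error at line %d: block has no MATRIX statement",
                 begin))
  rows <- character(0); row_lines <- integer(0)
  i <- mat_ln[1] + 1
  while (i <= length(block)) {
    ln <- trimws(block[i])
    if (grepl("^;", ln)) break
    if (nzchar(ln)) { rows <- c(rows, sub(";\\s*$", "", ln))
                      row_lines <- c(row_lines, block_start + i - 1) }
    if (grepl(";\\s*$", ln)) break
    i <- i + 1
  }
  if (i > length(block))
    stop(sprintf("parse error at line %d: MATRIX not terminated by ';'",
                 block_start + mat_ln[1] - 1))

  taxa <- character(0); cells <- list()
  for (r in seq_along(rows)) {
    parsed <- .parse_matrix_row(rows[r], symbols, missing_ch, gap_ch,
                                row_lines[r])
    taxa <- c(taxa, parsed$taxon)
    cells[[length(cells) + 1L]] <- parsed$states
  }
  if (anyDuplicated(taxa))
    stop("validation error: duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  n_char <- unique(lengths(cells))
  if (length(n_char) != 1)
    stop("parse error: rows code different numbers of characters (",
         paste(n_char, collapse = ", "), ")")
  if (!is.na(n_char_decl) && n_char != n_char_decl)
    stop(sprintf("parse error: DIMENSIONS declares NCHAR=%d but rows have %d",
                 n_char_decl, n_char))
  states <- do.call(rbind, cells)
  rownames(states) <- taxa

  ordering <- .parse_assumptions(lines, low, n_char)
  character_matrix(states, ordering)
}

.strip_nexus_comments <- function(lines) {
  ## NEXUS comments are [...] and may span lines
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", "", txt)
  strsplit(txt, "\n", fixed = TRUE)[[1]]
}

.parse_matrix_row <- function(row, symbols, missing_ch, gap_ch, line_no) {
  row <- trimws(row)
  if (startsWith(row, "'")) {
    close <- regexpr("'", substring(row, 2), fixed = TRUE)
    if (close < 0)
      stop(sprintf("parse error at line %d: unterminated quoted taxon name",
                   line_no))
    taxon <- substring(row, 2, close)
    rest <- substring(row, close + 2)
  } else {
    sp <- regexpr("\\s", row)
    if (sp < 0)
      stop(sprintf("parse error at line %d: row has no character data",
                   line_no))
    taxon <- substring(row, 1, sp - 1)
    rest <- substring(row, sp + 1)
  }
  chars <- strsplit(gsub("\\s", "", rest), "")[[1]]
  states <- character(0)
  j <- 1
  to_int <- function(ch) {
    k <- match(ch, symbols)
    if (is.na(k))
      stop(sprintf("parse error at line %d: unknown symbol '%s'",
                   line_no, ch))
    k - 1L
  }
  while (j <= length(chars)) {
    ch <- chars[j]
    if (ch %in% c("(", "{")) {
      closer <- if (ch == "(") ")" else "}"
      k <- j + 1; grp <- integer(0)
      while (k <= length(chars) && chars[k] != closer) {
        if (chars[k] %in% c(missing_ch, gap_ch))
          stop(sprintf("parse error at line %d: '%s' inside polymorphism",
                       line_no, chars[k]))
        grp <- c(grp, to_int(chars[k])); k <- k + 1
      }
      if (k > length(chars))
        stop(sprintf("parse error at line %d: unclosed polymorphism",
                     line_no))
      states <- c(states, paste(sort(unique(grp)), collapse = "/"))
      j <- k + 1
    } else if (ch == missing_ch || ch == gap_ch) {
      states <- c(states, ""); j <- j + 1
    } else {
      states <- c(states, as.character(to_int(ch))); j <- j + 1
    }
  }
  list(taxon = taxon, states = states)
}

.parse_assumptions <- function(lines, low, n_char) {
  ordering <- rep("unordered", n_char)
  ab <- grep("begin\\s+assumptions\\s*;", low)
  if (!length(ab)) return(ordering)
  ends <- grep("^\\s*end\\s*;", low)
  ae <- ends[ends > ab[1]][1]
  if (is.na(ae))
    stop(sprintf("parse error at line %d: ASSUMPTIONS block lacks END;",
                 ab[1]))
  blk <- paste(lines[(ab[1] + 1):(ae - 1)], collapse = " ")
  ## DEFTYPE=ord makes ordered the default
  if (grepl("deftype\\s*=\\s*ord\\b", tolower(blk)))
    ordering[] <- "ordered"
  ## TYPESET ... = unord: 1-3 5, ord: 4 6-10;
  ts <- regmatches(blk, gregexpr("typeset[^;]*;", blk, ignore.case = TRUE))[[1]]
  for (t in ts) {
    body <- sub(".*=", "", sub(";\\s*$", "", t))
    groups <- strsplit(body, ",", fixed = TRUE)[[1]]
    for (g in groups) {
      parts <- strsplit(g, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2) next
      type <- trimws(tolower(parts[1]))
      flag <- if (type %in% c("ord", "ordered")) "ordered"
              else if (type %in% c("unord", "unordered")) "unordered"
              else next
      idx <- .parse_index_list(parts[2], n_char)
      ordering[idx] <- flag
    }
  }
  ordering
}

.parse_index_list <- function(txt, n_max) {
  toks <- strsplit(trimws(txt), "\\s+")[[1]]
  idx <- integer(0)
  for (tk in toks) {
    if (grepl("^[0-9]+-[0-9]+$", tk)) {
      ab <- as.integer(strsplit(tk, "-", fixed = TRUE)[[1]])
      idx <- c(idx, seq(ab[1], ab[2]))
    } else if (grepl("^[0-9]+$", tk)) {
      idx <- c(idx, as.integer(tk))
    }
  }
  idx[idx >= 1 & idx <= n_max]
}

#' Write a character matrix to NEXUS
#'
#' @param matrix a [character_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nexus_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "char_matrix"))
  cell_txt <- function(s) {
    if (s == "") return("?")
    if (grepl("/", s, fixed = TRUE))
      return(paste0("(", gsub("/", "", s, fixed = TRUE), ")"))
    s
  }
  rows <- vapply(seq_along(matrix$taxa), function(i) {
    paste0("'", matrix$taxa[i], "' ",
           paste(vapply(matrix$states[i, ], cell_txt, ""), collapse = ""))
  }, "")
  ord_idx <- which(matrix$ordering == "ordered")
  lines <- c(
    "#NEXUS",
    "BEGIN CHARACTERS;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
            length(matrix$taxa), matrix$n_char),
    '  FORMAT SYMBOLS="0123456789" MISSING=? GAP=-;',
    "  MATRIX",
    paste0("    ", rows),
    "  ;",
    "END;"
  )
  if (length(ord_idx)) {
    lines <- c(lines,
               "BEGIN ASSUMPTIONS;",
               sprintf("  TYPESET * default = ord: %s;",
                       paste(ord_idx, collapse = " ")),
               "END;")
  }
  writeLines(lines, path)
  invisible(path)
}
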
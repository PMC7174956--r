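## Reading and writing HHsuite .hhm profiles, score normalization, and
## dataset assembly. Only the match-state emission block is consumed: of
## each two-line match-state record, the first line carries the 20
## emission scores; the transition/diversity line, the NULL model line and
## all insert/delete information are skipped.

.isEmissionLine <- function(tok) {
  length(tok) >= 2L && grepl("^[A-Za-z-]$", tok[1L]) && grepl("^[0-9]+$", tok[2L])
}

.parseScoreToken <- function(tok, lineNo) {
  if (tok == "*") return(NA_integer_)
  if (!grepl("^[0-9]+$", tok)) {
    stop("hhm parse error at line ", lineNo, ": invalid score token '", tok, "'")
  }
  as.integer(tok)
}

#' Parse an HHsuite .hhm profile
#'
#' Reads the match-state emission block of an HHsuite v2/v3 `.hhm` file:
#' the 20 per-state emission scores between the `HMM` column-header line
#' and the `//` terminator. Scores are integers in HHM units
#' (about \eqn{-1000\log_2 p}); the `*` marker for negligible probability
#' is preserved as `NA`. The column order is taken from the file header
#' and carried in the returned object; it is never re-sorted.
#'
#' @param source path to a `.hhm` file, or a character vector of its lines.
#' @return an [HMMProfile].
#' @seealso [writeHHM()], [normalizeProfile()]
#' @export
parseHHM <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (inherits(source, "connection")) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }

  name <- NA_character_
  leng <- NA_integer_
  hmmLine <- NA_integer_
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (!length(tok)) next
    if (tok[1L] == "NAME" && length(tok) >= 2L) name <- tok[2L]
    if (tok[1L] == "LENG" && length(tok) >= 2L && grepl("^[0-9]+$", tok[2L])) {
      leng <- as.integer(tok[2L])
    }
    if (tok[1L] == "HMM") { hmmLine <- i; break }
  }
  if (is.na(hmmLine)) stop("hhm parse error: no 'HMM' column-header line found")
  headTok <- strsplit(trimws(lines[hmmLine]), "\\s+")[[1L]]
  if (length(headTok) < 21L) {
    stop("hhm parse error at line ", hmmLine,
         ": column header must list 20 amino-acid codes")
  }
  alpha <- headTok[2:21]
  if (!setequal(alpha, HH_ALPHABET) || anyDuplicated(alpha)) {
    stop("hhm parse error at line ", hmmLine,
         ": column header is not a permutation of the 20 standard amino acids")
  }

  scores <- list()
  residues <- character()
  i <- hmmLine + 1L
  terminated <- FALSE
  while (i <= length(lines)) {
    raw <- trimws(lines[i])
    if (raw == "//") { terminated <- TRUE; break }
    tok <- strsplit(raw, "\\s+")[[1L]]
    if (.isEmissionLine(tok)) {
      if (length(tok) != 22L) {
        stop("hhm parse error at line ", i, ": expected 20 emission fields, found ",
             length(tok) - 2L)
      }
      scores[[length(scores) + 1L]] <-
        vapply(tok[3:22], .parseScoreToken, integer(1), lineNo = i, USE.NAMES = FALSE)
      residues <- c(residues, tok[1L])
      i <- i + 2L  # skip the transition/diversity line of this record
    } else {
      i <- i + 1L  # header continuation, begin-state line, or blank
    }
  }
  if (!terminated) stop("hhm parse error: missing '//' terminator")
  if (!length(scores)) stop("hhm parse error: no match states found")
  L <- length(scores)
  if (!is.na(leng) && leng != L) {
    stop("hhm parse error: header declares LENG ", leng,
         " but body contains ", L, " match states")
  }
  mat <- do.call(rbind, scores)
  dimnames(mat) <- list(NULL, alpha)
  new("HMMProfile",
      proteinId = if (is.na(name)) "unnamed" else name,
      residues = paste(residues, collapse = ""),
      rawScores = mat,
      alphabet = alpha)
}

#' Write a minimal HHsuite-compatible .hhm file
#'
#' Emits a flat `.hhm` file that [parseHHM()] reads back to an equal
#' profile. Used for fixtures and for materializing synthetic datasets.
#'
#' @param profile an [HMMProfile].
#' @param sink output file path.
#' @return invisibly, the path written.
#' @export
writeHHM <- function(profile, sink) {
  stopifnot(is(profile, "HMMProfile"))
  validObject(profile)
  fmt <- function(x) ifelse(is.na(x), "*", as.character(x))
  res <- strsplit(profile@residues, "")[[1L]]
  L <- nrow(profile@rawScores)
  out <- c(
    "HHsearch 1.5",
    paste0("NAME  ", profile@proteinId),
    paste0("LENG  ", L, " match states, ", L, " columns in multiple alignment"),
    paste0("HMM    ", paste(profile@alphabet, collapse = "\t")),
    paste0("       ", paste(c("M->M", "M->I", "M->D", "I->M", "I->I",
                              "D->M", "D->D", "Neff", "Neff_I", "Neff_D"),
                            collapse = "\t")),
    paste0("       ", paste(c("0", "*", "*", "0", "*", "0", "*", "*", "*", "*"),
                            collapse = "\t")))
  for (i in seq_len(L)) {
    out <- c(out,
             paste(c(res[i], i, fmt(profile@rawScores[i, ])), collapse = "\t"),
             paste(c("", rep("0", 7L), "0", "0", "0"), collapse = "\t"))
  }
  out <- c(out, "//")
  con <- file(sink, open = "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(sink)
}

#' Normalize HHM scores into probabilities
#'
#' Applies the score-to-probability map entrywise: a STAR marker becomes
#' exactly 0 and an integer score `x` becomes `2^(-x/1000)`. Shape,
#' identifiers and column order are preserved; no further rescaling or
#' clipping is applied.
#'
#' @param profile an [HMMProfile].
#' @return a [NormalizedProfile] with entries in `[0, 1]`.
#' @export
normalizeProfile <- function(profile) {
  stopifnot(is(profile, "HMMProfile"))
  validObject(profile)
  m <- 2^(-profile@rawScores / 1000)
  m[is.na(m)] <- 0
  storage.mode(m) <- "double"
  new("NormalizedProfile",
      proteinId = profile@proteinId,
      residues = profile@residues,
      mat = m,
      alphabet = profile@alphabet)
}

#' Load a labeled profile dataset from disk
#'
#' Reads a two-column tab-separated label table (`id<TAB>0/1`; a header
#' row `id label` is tolerated) and one `<id>.hhm` profile per id from
#' `profileDir`, returning normalized profiles.
#'
#' @param profileDir directory containing one `.hhm` file per protein id.
#' @param labels path to the label TSV.
#' @return a [LabeledDataset].
#' @export
loadDataset <- function(profileDir, labels) {
  if (!file.exists(labels)) stop("labels file not found: ", labels)
  tab <- utils::read.table(labels, sep = "\t", header = FALSE,
                           colClasses = "character", strip.white = TRUE)
  if (ncol(tab) != 2L) stop("labels file must have exactly two columns (id, 0/1)")
  if (nrow(tab) && !tab[1L, 2L] %in% c("0", "1")) tab <- tab[-1L, , drop = FALSE]
  if (!nrow(tab)) stop("labels file contains no entries")
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate protein ids in labels file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!all(tab[[2L]] %in% c("0", "1"))) stop("labels must be 0 or 1")
  y <- as.integer(tab[[2L]])
  if (length(unique(y)) < 2L) stop("labels file must contain both classes")
  paths <- file.path(profileDir, paste0(ids, ".hhm"))
  missing <- ids[!file.exists(paths)]
  if (length(missing)) {
    stop("no .hhm profile found for id(s): ", paste(missing, collapse = ", "))
  }
  profiles <- lapply(paths, function(p) normalizeProfile(parseHHM(p)))
  new("LabeledDataset", proteinIds = ids, profiles = profiles, labels = y)
}
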
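# Encounter-history container and its on-disk dialects (.inp and CSV mirror).

#' Encounter-history set
#'
#' One row per individual: an observed state code per occasion
#' (0 = not encountered, 1 = breeder, 2 = nonbreeder, 3 = prebreeder), plus
#' the individual's colony. Codes before the first encounter are 0, the code
#' at the first encounter is non-zero, and (by the classification rules) no
#' prebreeder code appears after the first breeder code.
#'
#' @param id character vector of individual ids.
#' @param colony factor (or character) of colony names, one per individual.
#' @param codes integer matrix `individuals x occasions` over 0:3.
#' @param years calendar years labelling the occasions.
#' @return object of class `msmr_histories`.
#' @export
new_histories <- function(id, colony, codes, years) {
  codes <- matrix(as.integer(codes), nrow = length(id))
  if (!is.factor(colony)) colony <- factor(colony)
  .assert(nrow(codes) == length(id) && length(colony) == length(id),
    "id, colony and codes must agree in length")
  .assert(ncol(codes) == length(years), "codes must have one column per year")
  .assert(all(codes %in% 0:3), "codes must be in 0:3")
  first <- apply(codes != 0L, 1L, function(z) if (any(z)) which(z)[1] else NA_integer_)
  .assert(!anyNA(first), "every history must contain at least one encounter")
  structure(list(id = as.character(id), colony = colony, codes = codes,
    first_occasion = as.integer(first), years = as.integer(years)),
    class = "msmr_histories")
}

#' @export
print.msmr_histories <- function(x, ...) {
  cat(sprintf("Encounter histories: %d individuals, %d occasions (%d-%d)\n",
    length(x$id), ncol(x$codes), min(x$years), max(x$years)))
  print(table(colony = x$colony))
  invisible(x)
}

#' @export
`[.msmr_histories` <- function(x, i, ...) {
  new_histories(x$id[i], x$colony[i], x$codes[i, , drop = FALSE], x$years)
}

#' @rdname new_histories
#' @param x object to test.
#' @export
is_histories <- function(x) inherits(x, "msmr_histories")

#' Read and write encounter histories
#'
#' Two dialects are supported and round-trip exactly:
#' \describe{
#'   \item{`.inp`}{one line per individual:
#'     `/* id */ SSSSSSSS f_1 f_2 ... ;` where `S` is the state digit per
#'     occasion and `f_k` are 1/0 colony-group frequency columns in the order
#'     of `colonies`.}
#'   \item{CSV}{columns `individual_id`, `colony`, then `code_<year>` per
#'     occasion; a `# years:` comment records the occasion labels.}
#' }
#'
#' @param histories an [msmr_histories] object.
#' @param path file path.
#' @param comments extra comment lines (without comment markers) written into
#'   the file header, e.g. a config hash.
#' @export
write_inp <- function(histories, path, comments = character()) {
  cols <- levels(histories$colony)
  lines <- vapply(seq_along(histories$id), function(i) {
    freq <- as.integer(cols == as.character(histories$colony[i]))
    sprintf("/* %s */ %s %s ;", histories$id[i],
      paste(histories$codes[i, ], collapse = ""),
      paste(freq, collapse = " "))
  }, character(1))
  hdr <- if (length(comments)) sprintf("/* %s */", comments) else character()
  writeLines(c(hdr,
    sprintf("/* occasions: %s */", paste(histories$years, collapse = " ")),
    sprintf("/* groups: %s */", paste(cols, collapse = " ")), lines), path)
  invisible(path)
}

#' @rdname write_inp
#' @param colonies colony names for the frequency columns; when `NULL` they
#'   are taken from the `/* groups: ... */` header comment.
#' @param years occasion labels; when `NULL` taken from the header comment.
#' @export
read_inp <- function(path, colonies = NULL, years = NULL) {
  lines <- readLines(path)
  hdr_years <- grep("^/\\* occasions:", lines, value = TRUE)
  hdr_groups <- grep("^/\\* groups:", lines, value = TRUE)
  if (is.null(years) && length(hdr_years)) {
    years <- as.integer(strsplit(sub("^/\\* occasions: *(.*?) *\\*/$", "\\1",
      hdr_years[1]), " +")[[1]])
  }
  if (is.null(colonies) && length(hdr_groups)) {
    colonies <- strsplit(sub("^/\\* groups: *(.*?) *\\*/$", "\\1",
      hdr_groups[1]), " +")[[1]]
  }
  body <- grep(";\\s*$", lines, value = TRUE)
  .assert(length(body) > 0, "no history lines found in %s", path)
  id <- sub("^/\\* *(.*?) *\\*/.*$", "\\1", body, perl = TRUE)
  rest <- sub("^/\\*.*?\\*/ *", "", body, perl = TRUE)
  rest <- sub(" *; *$", "", rest)
  parts <- strsplit(rest, " +")
  hist_str <- vapply(parts, `[[`, character(1), 1L)
  freqs <- matrix(vapply(parts, function(p) as.integer(p[-1]),
    integer(length(colonies))), nrow = length(colonies))
  codes <- do.call(rbind, lapply(strsplit(hist_str, ""), as.integer))
  if (is.null(years)) years <- seq_len(ncol(codes))
  colony <- factor(colonies[apply(freqs, 2L, which.max)], levels = colonies)
  new_histories(id, colony, codes, years)
}

#' @rdname write_inp
#' @export
write_histories_csv <- function(histories, path, comments = character()) {
  df <- data.frame(individual_id = histories$id,
    colony = as.character(histories$colony))
  codes <- histories$codes
  colnames(codes) <- paste0("code_", histories$years)
  df <- cbind(df, as.data.frame(codes))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- if (length(comments)) sprintf("# %s", comments) else character()
  writeLines(c(hdr,
    sprintf("# years: %s", paste(histories$years, collapse = " "))), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_inp
#' @export
read_histories_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  code_cols <- grep("^code_", names(df), value = TRUE)
  years <- as.integer(sub("^code_", "", code_cols))
  new_histories(df$individual_id, df$colony,
    as.matrix(df[, code_cols, drop = FALSE]), years)
}
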
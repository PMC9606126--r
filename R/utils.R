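# Internal helpers: seeding, delimiter detection, tiny hashing.

#' Derive a reproducible child seed from a master seed and a string key
#'
#' Deterministic splitting rule used wherever the package needs independent
#' random streams per site or per stage: the child seed depends only on the
#' master seed and the key (e.g. a site id), never on iteration order, so
#' reordering sites cannot change results. Kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param key character scalar naming the stream.
#' @return an integer seed.
#' @export
child_seed <- function(master, key) {
  stopifnot(length(master) == 1L, is.finite(master), is.character(key), length(key) == 1L)
  u <- utf8ToInt(key)
  h <- sum(u * seq_along(u)) %% 1048573
  as.integer((abs(as.double(master)) * 7919 + h * 104729 + 17) %% 2147483629)
}

# run `code` under a temporary RNG seed; NULL seed = use current stream
with_seed_ <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# delimiter from file extension: .csv -> comma, .tsv/.txt -> tab
detect_delim <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = ",", tsv = "\t", txt = "\t",
         stop("cannot infer delimiter from extension '.", ext, "' (use .csv or .tsv)", call. = FALSE))
}

read_delim_file <- function(path) {
  utils::read.table(path, header = TRUE, sep = detect_delim(path),
                    comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"")
}

write_delim_file <- function(df, path, header_lines = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  utils::write.table(df, con, sep = detect_delim(path), row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

# small stable hash of an R object (polynomial rolling hash over its
# deparsed form); used for provenance stamps only
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 536870909
  sprintf("%08x", as.integer(h))
}

is_wholenumber <- function(x, tol = 1e-8) is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol

`%||%` <- function(a, b) if (is.null(a)) b else a
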
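# Report writers, MEME minimal motif format, and the pipeline driver.

memeSymbols <- function(L) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (L <= length(pool)) pool[seq_len(L)]
  else paste0("T", seq_len(L))  # multi-character symbols, tabled in header
}

#' Write PWMs in MEME minimal motif format
#'
#' Cell-type codes are mapped to single-character alphabet symbols
#' (A, B, ...; falling back to multi-character symbols \code{T1, T2, ...}
#' listed in a header comment when more than 62 types are present).
#'
#' @param pwms list of \code{\link{Pwm}} (or a single one); names become
#'   motif names.
#' @param path output file
#' @param nsites optional per-motif site counts
#' @return invisibly, the path
#' @export
writeMemeMinimal <- function(pwms, path, nsites = NULL) {
  if (is(pwms, "Pwm")) pwms <- list(motif1 = pwms)
  if (is.null(names(pwms)) || any(names(pwms) == ""))
    names(pwms) <- paste0("motif", seq_along(pwms))
  L <- nrow(pwms[[1L]]@mat)
  sym <- memeSymbols(L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", ""), con)
  if (any(nchar(sym) > 1)) {
    writeLines(paste0("# symbol table: ",
                      paste(sprintf("%s=%d", sym, seq_len(L)),
                            collapse = " ")), con)
  }
  writeLines(c(paste0("ALPHABET= ", paste(sym, collapse = "")), ""), con)
  b <- pwms[[1L]]@background
  b <- b / sum(b)
  writeLines("Background letter frequencies", con)
  writeLines(paste(paste(sym, sprintf("%.6f", b)), collapse = " "), con)
  writeLines("", con)
  for (i in seq_along(pwms)) {
    M <- pwms[[i]]@mat
    ns <- if (is.null(nsites)) 20L else nsites[i]
    writeLines(sprintf("MOTIF %s", names(pwms)[i]), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= %d w= %d nsites= %d E= 0",
      L, ncol(M), ns), con)
    for (j in seq_len(ncol(M)))
      writeLines(paste(sprintf("%.9f", M[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a MEME minimal motif file
#'
#' @param path file written by \code{\link{writeMemeMinimal}} or any
#'   minimal-format motif file with a single alphabet
#' @return named list of \code{\link{Pwm}}
#' @export
readMemeMinimal <- function(path) {
  ln <- readLines(path)
  if (!any(grepl("^MEME version", ln)))
    stop("'", path, "' is not a MEME minimal motif file")
  bgLine <- which(grepl("^Background letter frequencies", ln))
  bg <- numeric(0)
  if (length(bgLine)) {
    toks <- strsplit(trimws(ln[bgLine[1] + 1L]), "\\s+")[[1]]
    bg <- as.numeric(toks[seq(2, length(toks), by = 2)])
  }
  starts <- which(grepl("^MOTIF ", ln))
  out <- list()
  for (s in starts) {
    nm <- sub("^MOTIF\\s+(\\S+).*", "\\1", ln[s])
    hd <- ln[s + 1L]
    L <- as.integer(sub(".*alength=\\s*(\\d+).*", "\\1", hd))
    W <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hd))
    rows <- vapply(ln[(s + 2L):(s + 1L + W)], function(x)
      as.numeric(strsplit(trimws(x), "\\s+")[[1]]),
      numeric(L))
    M <- matrix(rows, nrow = L)  # columns = positions
    M <- sweep(M, 2, colSums(M), "/")
    if (!length(bg)) bg <- rep(1 / L, L)
    out[[nm]] <- new("Pwm", mat = M, background = bg / sum(bg), rho = 0)
  }
  out
}

#' Write a motif report
#'
#' TSV summary (rank, consensus word, log10 p train and score, member and
#' occurrence counts) plus a JSON file with the full PWMs and per-section
#' occupied nodes (0-based at the file boundary), and a MEME minimal file
#' of the PWMs.
#'
#' @param fit a \code{\link{SmoreFit}}
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
writeMotifReport <- function(fit, dir) {
  stopifnot(is(fit, "SmoreFit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ms <- motifs(fit)
  typeNames <- cellTypes(fit@graphs[[1L]])
  tsv <- data.frame(
    rank = vapply(ms, function(m) m@rank, integer(1)),
    consensus = vapply(ms, function(m)
      formatWord(m@consensus, typeNames), character(1)),
    log10_p_train = vapply(ms, function(m) m@logPTrain, numeric(1)),
    log10_p_score = vapply(ms, function(m) m@logPScore, numeric(1)),
    n_members = vapply(ms, function(m) nrow(m@members), integer(1)),
    n_occurrences = vapply(ms, function(m) sum(m@members$Z), integer(1)))
  data.table::fwrite(tsv, file.path(dir, "motifs.tsv"), sep = "\t")
  js <- lapply(ms, function(m) list(
    rank = m@rank,
    consensus = formatWord(m@consensus, typeNames),
    log10_p_train = m@logPTrain,
    log10_p_score = m@logPScore,
    score_threshold = m@scoreThreshold,
    pwm = unname(as.data.frame(m@pwm@mat)),
    members = m@members[, c("word", "Z", "N", "P")],
    occupied_nodes = lapply(m@occupiedNodes, function(v) v - 1L)))
  jsonlite::write_json(js, file.path(dir, "motifs.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(ms))
    writeMemeMinimal(stats::setNames(lapply(ms, function(m) m@pwm),
                                     paste0("motif", seq_along(ms))),
                     file.path(dir, "motifs.meme"),
                     nsites = vapply(ms, function(m) sum(m@members$Z),
                                     integer(1)))
  invisible(dir)
}

#' Run the full pipeline from a configuration
#'
#' Reads the cell table, builds per-section graphs, samples paths, runs
#' motif discovery, and writes the graph files, sampled paths, motif
#' report and the resolved configuration (JSON, lossless round trip) into
#' the output directory.
#'
#' @param config named list (or path to a JSON file) with elements:
#'   \code{input} (cell table path), \code{outdir}, \code{graph} (list:
#'   method, param), \code{sampling} (list: k, level, radial),
#'   \code{control} (list: method, K, fixedTypes, nTrain, nScore),
#'   \code{discovery} (list: W, nEval, nRef, nEnrich, differentialP,
#'   maxMotifs, stopLogP), \code{seed}.
#' @return invisibly, the \code{\link{SmoreFit}}
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- list(
    graph = list(method = "delaunay", param = NULL),
    sampling = list(k = NULL, level = 1, radial = TRUE),
    control = list(method = "shuffle", K = 1, fixedTypes = list(),
                   nTrain = 10, nScore = 50),
    discovery = list(W = 4, nEval = 25, nRef = 4, nEnrich = 20,
                     differentialP = FALSE, maxMotifs = 10, stopLogP = -3),
    seed = 1)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$input) || is.null(config$outdir))
    stop("config must provide 'input' and 'outdir'")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(config, file.path(config$outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cells <- readCellTable(config$input)
  graphs <- buildGraph(cells, method = config$graph$method,
                       param = config$graph$param)
  for (sec in names(graphs))
    writeGraph(graphs[[sec]],
               file.path(config$outdir, paste0("nodes_", sec, ".tsv")),
               file.path(config$outdir, paste0("edges_", sec, ".tsv")))

  W <- config$discovery$W
  k <- if (is.null(config$sampling$k)) W else config$sampling$k
  fit <- discoverMotifs(graphs, W = W, k = k,
                        level = config$sampling$level,
                        radial = isTRUE(config$sampling$radial),
                        controlMethod = config$control$method,
                        kernelK = config$control$K,
                        fixedTypes = unlist(config$control$fixedTypes),
                        nTrain = config$control$nTrain,
                        nScore = config$control$nScore,
                        nEval = config$discovery$nEval,
                        nRef = config$discovery$nRef,
                        nEnrich = config$discovery$nEnrich,
                        differentialP = isTRUE(config$discovery$differentialP),
                        maxMotifs = config$discovery$maxMotifs,
                        stopLogP = config$discovery$stopLogP,
                        seed = config$seed)
  for (sec in names(graphs)) {
    ps <- samplePaths(graphs[[sec]], k, level = config$sampling$level,
                      radial = isTRUE(config$sampling$radial),
                      seed = deriveSeed(config$seed, "sample",
                                        match(sec, names(graphs))))
    writePaths(ps, graphs[[sec]],
               file.path(config$outdir, paste0("paths_", sec, ".tsv")))
  }
  writeMotifReport(fit, config$outdir)
  invisible(fit)
}
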
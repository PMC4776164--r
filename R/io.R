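#' Read an OTU count table from TSV
#'
#' Canonical dialect: tab-separated, UTF-8, '.' decimal; header row of sample
#' ids, first column of taxon ids, integer cells.  Row and column order are
#' preserved.
#'
#' @param path file path.
#' @return integer matrix, taxa x samples, with dimnames.
#' @export
readOtuTable <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop("OTU table needs a taxon-id column plus >=1 sample column")
  taxa <- raw[[1]]
  if (anyDuplicated(taxa)) stop("duplicate taxon ids: ",
    paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples)) stop("duplicate sample ids: ",
    paste(unique(samples[duplicated(samples)]), collapse = ", "))
  m <- matrix(NA_integer_, nrow(raw), length(samples),
              dimnames = list(taxa, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop(sprintf("non-integer or negative count at row '%s', column '%s': '%s'",
                   taxa[bad[1]], samples[j], raw[[j + 1L]][bad[1]]))
    m[, j] <- as.integer(v)
  }
  m
}

#' Write an OTU count table to TSV
#'
#' @param counts integer matrix, taxa x samples, with dimnames.
#' @param path file path.
#' @param idColumn name of the first (taxon id) column.
#' @export
writeOtuTable <- function(counts, path, idColumn = "taxon_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted newick tree
#'
#' Parentheses are balance-checked first so malformed input fails with the
#' character offset of the first unmatched token; parsing is then delegated
#' to [ape::read.tree()].  Edges without branch lengths are set to 0 with a
#' warning.  Quoted labels and unlabeled internal nodes are allowed.
#'
#' @param text newick string, or a path to a file containing one.
#' @return an `ape::phylo` tree.
#' @export
readNewick <- function(text) {
  if (length(text) == 1 && !grepl("(", text, fixed = TRUE) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  quoted <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("newick parse error: unmatched ')' at character %d", i))
    }
  }
  if (depth > 0L)
    stop(sprintf("newick parse error: %d unclosed '(' (last at character %d)",
                 depth, max(which(chars == "("))))
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("newick parse error: ape could not parse the string")
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning(sum(is.na(tr$edge.length)), " missing branch length(s) set to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Read and join sampling design and environmental tables
#'
#' Both TSVs are keyed by `sample_id`.  Samples present in only one file are
#' reported with a warning; their environmental rows are flagged missing
#' (all NA).  Missing env values (empty cell or "NA") stay missing.
#'
#' @param pathDesign TSV with columns sample_id, season, site, spatial_group.
#' @param pathEnv TSV with sample_id plus environmental columns.
#' @return list with elements `design` and `env`, both data.frames keyed by
#'   rowname, env aligned to the design's samples.
#' @export
readDesignEnv <- function(pathDesign, pathEnv) {
  design <- utils::read.delim(pathDesign, stringsAsFactors = FALSE)
  needed <- c("sample_id", "season", "site", "spatial_group")
  if (!all(needed %in% colnames(design)))
    stop("design file must have columns: ", paste(needed, collapse = ", "))
  grpPerSite <- unique(design[, c("site", "spatial_group")])
  if (anyDuplicated(grpPerSite$site)) {
    bad <- grpPerSite$site[duplicated(grpPerSite$site)]
    stop("spatial_group is not constant within site(s): ",
         paste(unique(bad), collapse = ", "))
  }
  env <- utils::read.delim(pathEnv, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"sample_id" %in% colnames(env)) stop("env file must have a sample_id column")
  onlyDesign <- setdiff(design$sample_id, env$sample_id)
  onlyEnv <- setdiff(env$sample_id, design$sample_id)
  if (length(onlyDesign))
    warning("samples missing from env file (flagged NA): ",
            paste(onlyDesign, collapse = ", "))
  if (length(onlyEnv))
    warning("samples present only in env file (dropped): ",
            paste(onlyEnv, collapse = ", "))
  rownames(design) <- design$sample_id
  rownames(env) <- env$sample_id
  envAligned <- env[match(design$sample_id, env$sample_id), -1, drop = FALSE]
  rownames(envAligned) <- design$sample_id
  badNeg <- vapply(colnames(envAligned), function(v) {
    x <- envAligned[[v]]
    is.numeric(x) && v != "temperature" && any(x < 0, na.rm = TRUE)
  }, logical(1))
  if (any(badNeg))
    stop("negative values in non-negative env variable(s): ",
         paste(names(badNeg)[badNeg], collapse = ", "))
  list(design = design[, -1, drop = FALSE], env = envAligned)
}

#' Read DGGE band patterns from CSV
#'
#' Expected columns: `lane_id`, `position` (relative migration in \[0, 1\]),
#' `height` (non-negative densitometric peak height).
#'
#' @param path CSV file path.
#' @return named list of data.frames (one per lane, in file order), each with
#'   strictly increasing `position` and `height` columns.
#' @export
readBandPatterns <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lane_id", "position", "height") %in% colnames(raw)))
    stop("band file must have columns lane_id, position, height")
  lanes <- split(raw[, c("position", "height")], factor(raw$lane_id, unique(raw$lane_id)))
  lapply(lanes, function(df) {
    df <- df[order(df$position), , drop = FALSE]
    if (any(diff(df$position) <= 0))
      stop("band positions must be strictly increasing within a lane")
    if (any(df$height < 0)) stop("band heights must be non-negative")
    rownames(df) <- NULL
    df
  })
}

#' Write DGGE band patterns to CSV
#'
#' @param patterns named list of data.frames as returned by [readBandPatterns()].
#' @param path CSV file path.
#' @export
writeBandPatterns <- function(patterns, path) {
  df <- do.call(rbind, lapply(names(patterns), function(id)
    data.frame(lane_id = id, patterns[[id]], stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a square distance matrix as TSV with ids
#'
#' @param d a `dist` object (for writing) or file path (for reading).
#' @param path file path.
#' @return `writeDistanceMatrix` returns the path; `readDistanceMatrix`
#'   returns a `dist`.
#' @export
writeDistanceMatrix <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(d) {
  raw <- utils::read.delim(d, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  stats::as.dist(m)
}

#' Write a sampling design / environmental table to TSV
#'
#' @param x data.frame keyed by rownames (sample ids).
#' @param path file path.
#' @export
writeSampleTable <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as.data.frame(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
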
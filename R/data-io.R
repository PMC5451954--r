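## data_io module: constructors, readers and writers for count panels,
## adjacency and covariates, with index-alignment validation.

#' Construct a StudyFrame
#'
#' @param countyIds character county labels (length I).
#' @param years integer consecutive calendar years (length J).
#' @param diseaseIds character disease labels (length K <= 3).
#' @param counts I x J x K array of non-negative integer counts (true or
#'   threshold-coded).
#' @param populations I x J matrix of positive populations at risk, or a
#'   length-I vector recycled over years.
#' @param expected optional I x J x K array of expected counts.
#' @param coded optional I x J x K logical mask of threshold-coded
#'   cells; defaults to all-FALSE.
#' @param imputed logical flag.
#' @return a \code{\linkS4class{StudyFrame}}
#' @export
studyFrame <- function(countyIds, years, diseaseIds, counts, populations,
                       expected = NULL, coded = NULL, imputed = FALSE) {
  I <- length(countyIds); J <- length(years); K <- length(diseaseIds)
  if (is.vector(populations) && length(populations) == I)
    populations <- matrix(populations, I, J)
  if (is.null(coded)) coded <- array(FALSE, c(I, J, K))
  if (is.null(expected)) expected <- array(NA_real_, c(I, J, K))
  dimnames(counts) <- dimnames(expected) <- dimnames(coded) <-
    list(countyIds, years, diseaseIds)
  dimnames(populations) <- list(countyIds, years)
  new("StudyFrame", countyIds = as.character(countyIds),
      years = as.integer(years), diseaseIds = as.character(diseaseIds),
      counts = counts, populations = populations, expected = expected,
      coded = coded, imputed = imputed)
}

#' Construct an AdjacencyGraph from an edge list
#'
#' @param countyIds character county labels.
#' @param edges two-column matrix/data.frame of county label pairs, or a
#'   list of neighbor index vectors.
#' @param symmetrize if TRUE (default), a one-directional edge implies
#'   its reverse, with a warning.
#' @return an \code{\linkS4class{AdjacencyGraph}}
#' @export
adjacencyGraph <- function(countyIds, edges, symmetrize = TRUE) {
  countyIds <- as.character(countyIds)
  I <- length(countyIds)
  nb <- vector("list", I)
  for (i in seq_len(I)) nb[[i]] <- integer(0)
  if (is.list(edges) && !is.data.frame(edges)) {
    nb <- lapply(edges, as.integer)
  } else {
    edges <- as.matrix(edges)
    a <- match(as.character(edges[, 1]), countyIds)
    b <- match(as.character(edges[, 2]), countyIds)
    if (anyNA(a) || anyNA(b))
      .stopf("edge refers to unknown county: %s",
             paste(unique(c(edges[, 1][is.na(a)], edges[, 2][is.na(b)])),
                   collapse = ", "))
    if (any(a == b)) .stopf("self-edge at county '%s'", countyIds[a[a == b][1]])
    asym <- FALSE
    pair <- paste(pmin(a, b), pmax(a, b))
    for (p in unique(pair)) {
      idx <- which(pair == p)
      i <- a[idx[1]]; l <- b[idx[1]]
      if (!(any(a[idx] == i & b[idx] == l) && any(a[idx] == l & b[idx] == i)))
        asym <- TRUE
      nb[[i]] <- union(nb[[i]], l)
      nb[[l]] <- union(nb[[l]], i)
    }
    if (asym && symmetrize)
      .warnf("edge list was not symmetric; missing reverse edges were added")
  }
  nb <- lapply(nb, function(x) sort(as.integer(x)))
  iso <- which(lengths(nb) == 0L)
  if (length(iso))
    .stopf("isolated county with no neighbors: %s",
           paste(countyIds[iso], collapse = ", "))
  new("AdjacencyGraph", countyIds = countyIds, neighbors = nb,
      nNeighbors = lengths(nb))
}

#' Construct a CovariateSet
#'
#' @param spatial I x P_S matrix or NULL.
#' @param temporal J x P_T matrix or NULL.
#' @param spacetime I x J x P_ST array or NULL.
#' @param I,J grid dimensions, required when a block is NULL.
#' @return a \code{\linkS4class{CovariateSet}}
#' @export
covariateSet <- function(spatial = NULL, temporal = NULL, spacetime = NULL,
                         I = NULL, J = NULL) {
  if (is.null(spatial)) spatial <- matrix(0, I %||% 0L, 0L)
  if (is.null(temporal)) temporal <- matrix(0, J %||% 0L, 0L)
  spatial <- as.matrix(spatial); temporal <- as.matrix(temporal)
  if (is.null(spacetime))
    spacetime <- array(0, c(if (nrow(spatial)) nrow(spatial) else I %||% 0L,
                            if (nrow(temporal)) nrow(temporal) else J %||% 0L,
                            0L))
  new("CovariateSet", spatial = spatial, temporal = temporal,
      spacetime = spacetime, standardized = FALSE,
      centers = list(), scales = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a long-format count panel
#'
#' Reads a CSV with columns \code{county, year, disease, count,
#' population} and optionally \code{coded} (0/1), and validates that the
#' rows form a complete county x year x disease grid.
#'
#' @param path CSV file path.
#' @return a \code{\linkS4class{StudyFrame}}
#' @export
readCounts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("county", "year", "disease", "count", "population")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("counts file lacks column(s): %s",
                           paste(miss, collapse = ", "))
  countyIds <- sort(unique(as.character(df$county)))
  years <- sort(unique(as.integer(df$year)))
  diseaseIds <- sort(unique(as.character(df$disease)))
  I <- length(countyIds); J <- length(years); K <- length(diseaseIds)
  key <- paste(df$county, df$year, df$disease, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) .stopf("duplicate cell (county=%s, year=%s, disease=%s)",
                       df$county[dup][1], df$year[dup][1], df$disease[dup][1])
  full <- expand.grid(county = countyIds, year = years, disease = diseaseIds,
                      stringsAsFactors = FALSE)
  fullKey <- paste(full$county, full$year, full$disease, sep = "\r")
  missIdx <- which(!(fullKey %in% key))
  if (length(missIdx))
    .stopf("missing cell (county=%s, year=%s, disease=%s)",
           full$county[missIdx[1]], full$year[missIdx[1]],
           full$disease[missIdx[1]])
  if (any(df$population <= 0)) {
    bad <- which(df$population <= 0)[1]
    .stopf("non-positive population at (county=%s, year=%s)",
           df$county[bad], df$year[bad])
  }
  ord <- match(fullKey, key)
  counts <- array(as.numeric(df$count[ord]), c(I, J, K))
  pops <- matrix(as.numeric(df$population[ord[seq_len(I * J)]]), I, J)
  ## population must be consistent across diseases for the same (i,j)
  for (k in seq_len(K)[-1]) {
    pk <- matrix(as.numeric(df$population[ord[(k - 1) * I * J + seq_len(I * J)]]), I, J)
    if (!isTRUE(all.equal(pk, pops)))
      .stopf("population differs across diseases for the same county-year")
  }
  coded <- if ("coded" %in% names(df))
    array(as.logical(df$coded[ord]), c(I, J, K)) else NULL
  studyFrame(countyIds, years, diseaseIds, counts, pops, coded = coded)
}

#' Write a StudyFrame as long-format CSV
#'
#' @param frame a \code{StudyFrame}.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeCounts <- function(frame, path) {
  d <- dim(frame)
  full <- expand.grid(county = frame@countyIds, year = frame@years,
                      disease = frame@diseaseIds, stringsAsFactors = FALSE)
  full$count <- as.vector(frame@counts)
  full$population <- rep(as.vector(frame@populations), d[3])
  full$coded <- as.integer(as.vector(frame@coded))
  utils::write.csv(full, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read county adjacency (GAL or edge list)
#'
#' GAL format: a header line whose last-but-one token is the county
#' count (plain "n" headers also accepted), then for each county a line
#' "id nNeighbors" followed by a line with its neighbor ids.  Edge-list
#' format: two whitespace/comma-separated county labels per line
#' (optionally with a header "from,to").
#'
#' @param path file path; format chosen by extension (".gal") unless
#'   \code{format} is given.
#' @param format "gal", "edgelist" or "auto".
#' @param countyIds optional county labels to validate/align against.
#' @return an \code{\linkS4class{AdjacencyGraph}}
#' @export
readAdjacency <- function(path, format = c("auto", "gal", "edgelist"),
                          countyIds = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gal$", path, ignore.case = TRUE)) "gal" else "edgelist"
  if (format == "gal") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    n <- as.integer(if (length(hdr) >= 2) hdr[2] else hdr[1])
    ids <- character(n); nb <- vector("list", n)
    pos <- 2L
    for (r in seq_len(n)) {
      head <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
      ids[r] <- head[1]
      cnt <- as.integer(head[2])
      nb[[r]] <- strsplit(trimws(lines[pos + 1L]), "\\s+")[[1]]
      if (length(nb[[r]]) != cnt)
        .stopf("GAL neighbor count mismatch for county '%s'", ids[r])
      pos <- pos + 2L
    }
    edges <- do.call(rbind, lapply(seq_len(n), function(r)
      if (length(nb[[r]])) cbind(ids[r], nb[[r]]) else NULL))
    graph <- adjacencyGraph(ids, edges)
  } else {
    df <- utils::read.table(path, header = FALSE, sep = "",
                            stringsAsFactors = FALSE, comment.char = "#",
                            fill = TRUE)
    if (ncol(df) == 1L)
      df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
    ## drop a "from,to"-style header row if present
    if (tolower(df[1, 1]) %in% c("from", "county", "a")) df <- df[-1, ]
    ids <- sort(unique(c(as.character(df[, 1]), as.character(df[, 2]))))
    graph <- adjacencyGraph(ids, df[, 1:2])
  }
  if (!is.null(countyIds)) {
    countyIds <- as.character(countyIds)
    if (!setequal(graph@countyIds, countyIds))
      .stopf("adjacency counties do not match the study frame (e.g. %s)",
             paste(utils::head(c(setdiff(countyIds, graph@countyIds),
                                 setdiff(graph@countyIds, countyIds)), 3),
                   collapse = ", "))
    perm <- match(countyIds, graph@countyIds)
    inv <- match(graph@countyIds, countyIds)
    nb <- lapply(graph@neighbors[perm], function(v) sort(inv[v]))
    graph <- new("AdjacencyGraph", countyIds = countyIds, neighbors = nb,
                 nNeighbors = lengths(nb))
  }
  graph
}

#' Write an AdjacencyGraph in GAL format
#'
#' @param graph an \code{AdjacencyGraph}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeAdjacency <- function(graph, path) {
  n <- length(graph@countyIds)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("0 %d %s %s", n, "stmixmap", "counties"), con)
  for (i in seq_len(n)) {
    writeLines(sprintf("%s %d", graph@countyIds[i], graph@nNeighbors[i]), con)
    writeLines(paste(graph@countyIds[graph@neighbors[[i]]], collapse = " "), con)
  }
  invisible(path)
}

#' Read covariates from CSV files into a CovariateSet
#'
#' Spatial files are keyed by \code{county}, temporal by \code{year},
#' spatio-temporal by both; remaining columns are covariates.  Rows are
#' aligned to the frame's county/year order.
#'
#' @param frame a \code{StudyFrame} defining the index order.
#' @param spatialPath,temporalPath,spacetimePath CSV paths (each
#'   optional).
#' @return a \code{\linkS4class{CovariateSet}}
#' @export
readCovariates <- function(frame, spatialPath = NULL, temporalPath = NULL,
                           spacetimePath = NULL) {
  d <- dim(frame)
  sp <- tp <- NULL; st <- NULL
  if (!is.null(spatialPath)) {
    df <- utils::read.csv(spatialPath, stringsAsFactors = FALSE)
    idx <- match(frame@countyIds, as.character(df$county))
    if (anyNA(idx)) .stopf("spatial covariates missing county '%s'",
                           frame@countyIds[which(is.na(idx))[1]])
    sp <- as.matrix(df[idx, setdiff(names(df), "county"), drop = FALSE])
    rownames(sp) <- NULL
  }
  if (!is.null(temporalPath)) {
    df <- utils::read.csv(temporalPath, stringsAsFactors = FALSE)
    idx <- match(frame@years, as.integer(df$year))
    if (anyNA(idx)) .stopf("temporal covariates missing year %d",
                           frame@years[which(is.na(idx))[1]])
    tp <- as.matrix(df[idx, setdiff(names(df), "year"), drop = FALSE])
    rownames(tp) <- NULL
  }
  if (!is.null(spacetimePath)) {
    df <- utils::read.csv(spacetimePath, stringsAsFactors = FALSE)
    vars <- setdiff(names(df), c("county", "year"))
    st <- array(NA_real_, c(d[1], d[2], length(vars)),
                dimnames = list(NULL, NULL, vars))
    key <- paste(df$county, df$year, sep = "\r")
    want <- paste(rep(frame@countyIds, d[2]),
                  rep(frame@years, each = d[1]), sep = "\r")
    idx <- match(want, key)
    if (anyNA(idx)) .stopf("spatio-temporal covariates missing a county-year cell")
    for (v in seq_along(vars))
      st[, , v] <- matrix(df[[vars[v]]][idx], d[1], d[2])
  }
  covariateSet(sp, tp, st, I = d[1], J = d[2])
}

#' Standardize covariate columns
#'
#' Centers and scales every covariate column to mean 0 and (sample) SD 1
#' over its own index set, storing the constants so the transformation
#' can be undone.
#'
#' @param cov a \code{CovariateSet} with \code{isStandardized(cov)}
#'   FALSE.
#' @return the standardized \code{CovariateSet}.
#' @export
standardizeCovariates <- function(cov) {
  stopifnot(is(cov, "CovariateSet"))
  if (cov@standardized) .stopf("covariates are already standardized")
  centers <- scales <- list()
  stdMat <- function(m, what) {
    if (!ncol(m)) return(list(m = m, c = numeric(0), s = numeric(0)))
    cn <- colnames(m) %||% paste0(what, seq_len(ncol(m)))
    c0 <- colMeans(m)
    s0 <- apply(m, 2, stats::sd)
    if (any(s0 == 0))
      .stopf("zero-variance covariate column '%s'", cn[which(s0 == 0)[1]])
    list(m = sweep(sweep(m, 2, c0), 2, s0, "/"), c = stats::setNames(c0, cn),
         s = stats::setNames(s0, cn))
  }
  sp <- stdMat(cov@spatial, "S"); tp <- stdMat(cov@temporal, "T")
  st <- cov@spacetime
  stc <- sts <- numeric(0)
  if (dim(st)[3] > 0) {
    nm <- dimnames(st)[[3]] %||% paste0("ST", seq_len(dim(st)[3]))
    stc <- sts <- stats::setNames(numeric(dim(st)[3]), nm)
    for (p in seq_len(dim(st)[3])) {
      x <- st[, , p]
      stc[p] <- mean(x); sts[p] <- stats::sd(as.vector(x))
      if (sts[p] == 0) .stopf("zero-variance covariate column '%s'", nm[p])
      st[, , p] <- (x - stc[p]) / sts[p]
    }
  }
  new("CovariateSet", spatial = sp$m, temporal = tp$m, spacetime = st,
      standardized = TRUE,
      centers = list(spatial = sp$c, temporal = tp$c, spacetime = stc),
      scales = list(spatial = sp$s, temporal = tp$s, spacetime = sts))
}

#' Undo standardization using the stored constants
#'
#' @param cov a standardized \code{CovariateSet}.
#' @return the de-standardized \code{CovariateSet}.
#' @export
destandardizeCovariates <- function(cov) {
  stopifnot(is(cov, "CovariateSet"))
  if (!cov@standardized) .stopf("covariates are not standardized")
  sp <- cov@spatial; tp <- cov@temporal; st <- cov@spacetime
  if (ncol(sp)) sp <- sweep(sweep(sp, 2, cov@scales$spatial, "*"), 2,
                            cov@centers$spatial, "+")
  if (ncol(tp)) tp <- sweep(sweep(tp, 2, cov@scales$temporal, "*"), 2,
                            cov@centers$temporal, "+")
  if (dim(st)[3] > 0)
    for (p in seq_len(dim(st)[3]))
      st[, , p] <- st[, , p] * cov@scales$spacetime[p] + cov@centers$spacetime[p]
  new("CovariateSet", spatial = sp, temporal = tp, spacetime = st,
      standardized = FALSE, centers = list(), scales = list())
}
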
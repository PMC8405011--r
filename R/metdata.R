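#' Construct a multi-environment trial table
#'
#' Validates a long-format table of phenotypic records (one row per plot:
#' genotype, environment, block, response) and attaches the derived counts
#' used throughout the package: the number of genotypes `v`, environments
#' (locations) `l`, blocks `b`, replicates per genotype `r = b * l`, total
#' records `n`, and the maximal bilinear rank `t = min(v - 1, l)`.
#'
#' Genotype, environment and block identifiers are coerced to factors with
#' lexicographically sorted levels, so every downstream matrix and vector is
#' indexed in a fixed, reproducible order.
#'
#' @param data data frame with columns `genotype`, `environment`, `block`
#'   and `response` (names remappable through `col_map`).
#' @param col_map optional named character vector mapping the required names
#'   to the columns present in `data`, e.g.
#'   `c(genotype = "gen", response = "yield")`.
#' @return An object of class `"met_table"`: a list with elements
#'   `records` (data frame with factor keys and numeric response, input row
#'   order preserved), counts `v`, `l`, `b`, `r`, `n`, `t`, and
#'   `cell_counts`, a `v x l` matrix of observations per genotype-environment
#'   cell.
#' @seealso [read_met_table()], [build_design()], [center_gge_matrix()]
#' @export
met_table <- function(data, col_map = NULL) {
  wanted <- c("genotype", "environment", "block", "response")
  nm <- stats::setNames(wanted, wanted)
  if (!is.null(col_map)) nm[names(col_map)] <- col_map
  missing_cols <- nm[!nm %in% names(data)]
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  resp <- data[[nm["response"]]]
  if (!is.numeric(resp)) {
    resp_num <- suppressWarnings(as.numeric(as.character(resp)))
    bad <- which(is.na(resp_num) & !is.na(resp))
    if (length(bad))
      stop("non-numeric response in row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    resp <- resp_num
  }
  if (anyNA(resp)) stop("missing response values are not allowed", call. = FALSE)

  records <- data.frame(
    genotype    = factor(as.character(data[[nm["genotype"]]])),
    environment = factor(as.character(data[[nm["environment"]]])),
    block       = factor(as.character(data[[nm["block"]]])),
    response    = resp,
    stringsAsFactors = FALSE
  )
  key <- interaction(records$genotype, records$environment, records$block,
                     drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicated (genotype, environment, block) key(s), e.g. row ",
         which(duplicated(key))[1L], call. = FALSE)

  v <- nlevels(records$genotype)
  l <- nlevels(records$environment)
  b <- nlevels(records$block)
  if (v < 2L) stop("need at least 2 genotypes, found ", v, call. = FALSE)
  if (l < 2L) stop("need at least 2 environments, found ", l, call. = FALSE)
  if (b < 1L) stop("need at least 1 block", call. = FALSE)

  cell_counts <- table(records$genotype, records$environment)
  cell_counts <- matrix(as.integer(cell_counts), nrow = v, ncol = l,
                        dimnames = list(levels(records$genotype),
                                        levels(records$environment)))
  out <- list(
    records = records,
    v = v, l = l, b = b,
    r = b * l,
    n = nrow(records),
    t = min(v - 1L, l),
    cell_counts = cell_counts
  )
  class(out) <- "met_table"
  out
}

#' Read a multi-environment trial table from a delimited file
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @param col_map optional header remapping, as in [met_table()].
#' @return A validated [met_table()] object.
#' @export
read_met_table <- function(path, sep = ",", col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  met_table(raw, col_map = col_map)
}

#' @export
print.met_table <- function(x, ...) {
  cat("Multi-environment trial table\n")
  cat(sprintf("  %d records: %d genotypes x %d environments x %d blocks\n",
              x$n, x$v, x$l, x$b))
  cat(sprintf("  maximal bilinear rank t = %d\n", x$t))
  inc <- sum(x$cell_counts == 0L)
  if (inc) cat(sprintf("  %d empty genotype-environment cell(s)\n", inc))
  invisible(x)
}

#' Build incidence design matrices for the GGE model
#'
#' Constructs the three incidence matrices of the linear-bilinear model:
#' `X1` (`n x (b*l)`, block-within-environment; columns ordered
#' environment-major, block-minor), `X2` (`n x l`, environment) and `Z`
#' (`n x v`, genotype). Each row of each matrix contains a single 1.
#' Integer index vectors (`gi`, `ei`, `bi`, `x1i`) giving the column hit by
#' each record are returned alongside, and are what the samplers use.
#'
#' @param met a [met_table()] object.
#' @return An object of class `"met_design"`: list with `X1`, `X2`, `Z`,
#'   index vectors `gi`, `ei`, `bi`, `x1i`, the response vector `y` and the
#'   originating `met`.
#' @export
build_design <- function(met) {
  stopifnot(inherits(met, "met_table"))
  rec <- met$records
  gi <- as.integer(rec$genotype)
  ei <- as.integer(rec$environment)
  bi <- as.integer(rec$block)
  x1i <- (ei - 1L) * met$b + bi          # environment-major, block-minor
  n <- met$n
  incidence <- function(idx, ncol, colnames) {
    m <- matrix(0, n, ncol, dimnames = list(NULL, colnames))
    m[cbind(seq_len(n), idx)] <- 1
    m
  }
  bl_names <- as.vector(t(outer(levels(rec$environment), levels(rec$block),
                                paste, sep = ":")))
  out <- list(
    X1 = incidence(x1i, met$b * met$l, bl_names),
    X2 = incidence(ei, met$l, levels(rec$environment)),
    Z  = incidence(gi, met$v, levels(rec$genotype)),
    gi = gi, ei = ei, bi = bi, x1i = x1i,
    y = rec$response,
    met = met
  )
  class(out) <- "met_design"
  out
}

#' Environment-centered G+GE matrix of cell means
#'
#' Forms the `v x l` matrix of genotype-by-environment cell means and
#' subtracts each environment (column) mean. Centering by environment only
#' retains the genotype main effect inside the matrix, which is what the GGE
#' (site regression) decomposition analyses; no genotype centering is
#' applied.
#'
#' @param met a [met_table()] object with every cell observed at least once.
#' @return Object of class `"gge_matrix"`: the centered `v x l` matrix with
#'   attribute `cell_counts`.
#' @export
center_gge_matrix <- function(met) {
  stopifnot(inherits(met, "met_table"))
  if (any(met$cell_counts == 0L))
    stop("empty genotype-environment cell(s); the frequentist SVD path ",
         "requires complete cells. Fit the Bayesian model (bgge), which ",
         "handles missing cells through the design matrices.", call. = FALSE)
  rec <- met$records
  sums <- tapply(rec$response, list(rec$genotype, rec$environment), sum)
  means <- sums / met$cell_counts
  centered <- sweep(means, 2L, colMeans(means))
  structure(centered, cell_counts = met$cell_counts, class = "gge_matrix")
}

#' Singular value decomposition of a centered G+GE matrix
#'
#' Truncates to the maximal bilinear rank `t = min(v - 1, l)` and applies a
#' deterministic sign convention: within each environment loading the element
#' of largest magnitude is made positive (the genotype loading flips with
#' it), so repeated runs and different LAPACK builds give identical output.
#'
#' @param m a `v x l` matrix (typically from [center_gge_matrix()]).
#' @return List with `lambda` (nonincreasing singular values, length `t`),
#'   `A` (`v x t` genotype loadings) and `G` (`l x t` environment loadings),
#'   both with orthonormal columns.
#' @export
svd_gge <- function(m) {
  m <- unclass(m)
  v <- nrow(m); l <- ncol(m)
  t_rank <- min(v - 1L, l)
  s <- svd(m, nu = t_rank, nv = t_rank)
  A <- s$u
  G <- s$v
  for (k in seq_len(t_rank)) {
    j <- which.max(abs(G[, k]))
    if (G[j, k] < 0) { G[, k] <- -G[, k]; A[, k] <- -A[, k] }
  }
  rownames(A) <- rownames(m); rownames(G) <- colnames(m)
  list(lambda = s$d[seq_len(t_rank)], A = A, G = G)
}

#' Restrict a trial to a subset of environments
#'
#' Used for mega-environment analysis: after a global fit suggests subgroups
#' of environments with homogeneous winners, each subgroup is re-analysed on
#' its own. Counts and the maximal rank `t` are recomputed on the subset.
#'
#' @param met a [met_table()] object.
#' @param environments character vector of environment levels to keep.
#' @return A new [met_table()] restricted to those environments.
#' @export
subset_mega <- function(met, environments) {
  stopifnot(inherits(met, "met_table"))
  if (!length(environments)) stop("empty environment subset", call. = FALSE)
  keep <- met$records$environment %in% environments
  if (!any(keep)) stop("no records in the requested environments", call. = FALSE)
  rec <- met$records[keep, , drop = FALSE]
  rec$genotype <- droplevels(rec$genotype)
  rec$environment <- droplevels(rec$environment)
  rec$block <- droplevels(rec$block)
  met_table(rec)
}
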
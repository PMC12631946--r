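# Affinity records: unit conversion, curation, identity auditing, grouped
# cross-validation splits.

# gas constant, kcal/(mol K)
GAS_CONSTANT_KCAL <- 1.98720425e-3

#' Convert an affinity measurement to binding free energy
#'
#' `Kd`/`Ki` dissociation/inhibition constants convert through
#' `dG = R T ln(K)` with `R = 1.98720425e-3` kcal/(mol K); `Ki` is treated
#' as Kd-equivalent. Already-thermodynamic `dG` inputs pass through after a
#' unit check (kJ/mol is converted).
#'
#' @param value measured value (> 0 for Kd/Ki).
#' @param type `"Kd"`, `"Ki"` or `"dG"`.
#' @param unit for Kd/Ki one of `M`, `mM`, `uM`, `nM`, `pM`, `fM`; for dG
#'   `kcal/mol` or `kJ/mol`.
#' @param temperature Kelvin (default 298.15).
#' @return Binding free energy in kcal/mol.
#' @examples
#' affinity_to_dg(1, "Kd", "M")        # 0
#' affinity_to_dg(1, "Kd", "nM")       # about -12.28
#' @export
affinity_to_dg <- function(value, type = c("Kd", "Ki", "dG"), unit = "M",
                           temperature = 298.15) {
  type <- match.arg(type)
  if (type == "dG") {
    if (unit %in% c("kcal/mol", "kcal.mol-1")) return(value)
    if (unit %in% c("kJ/mol", "kj/mol")) return(value / 4.184)
    stop("unknown dG unit: ", unit)
  }
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12, fM = 1e-15)
  if (!unit %in% names(scale)) stop("unknown concentration unit: ", unit)
  if (any(value <= 0)) stop("Kd/Ki must be positive")
  k_molar <- value * scale[[unit]]
  GAS_CONSTANT_KCAL * temperature * log(k_molar)
}

#' Curate a table of affinity records
#'
#' Applies the standard cleaning rules and logs every action: entries whose
#' affinity type is not Kd/Ki/dG are dropped; range-valued affinities (a
#' non-`NA` `range_bound` column) are either replaced by the stated boundary
#' estimate (default) or dropped; repeated measurements of the same
#' (structure, mutation) are averaged on the dG scale; mutants whose parent
#' is absent are dropped as ambiguous.
#'
#' @param records data.frame with columns `structure_id`, `affinity_value`,
#'   `affinity_type`, `unit`, and optionally `temperature`, `is_mutant`,
#'   `parent_id`, `mutation`, `range_bound`.
#' @param keep_range_bounds use the boundary estimate for range-valued
#'   affinities (default) instead of dropping them.
#' @return List: `kept` (curated data.frame with a `dg` column, kcal/mol)
#'   and `audit` (data.frame of actions with reason codes).
#' @export
curate_records <- function(records, keep_range_bounds = TRUE) {
  stopifnot(is.data.frame(records))
  rec <- records
  if (is.null(rec$temperature)) rec$temperature <- 298.15
  if (is.null(rec$is_mutant)) rec$is_mutant <- FALSE
  if (is.null(rec$parent_id)) rec$parent_id <- rec$structure_id
  if (is.null(rec$mutation)) rec$mutation <- ""
  if (is.null(rec$range_bound)) rec$range_bound <- NA
  audit <- list()
  note <- function(id, code, detail = "") {
    audit[[length(audit) + 1L]] <<- data.frame(structure_id = id,
                                               code = code, detail = detail)
  }

  ok_type <- rec$affinity_type %in% c("Kd", "Ki", "dG")
  for (id in rec$structure_id[!ok_type]) note(id, "dropped_type")
  rec <- rec[ok_type, , drop = FALSE]

  ranged <- !is.na(rec$range_bound)
  if (any(ranged)) {
    if (keep_range_bounds) {
      rec$affinity_value[ranged] <- as.numeric(rec$range_bound[ranged])
      for (id in rec$structure_id[ranged]) note(id, "range_boundary_estimate")
    } else {
      for (id in rec$structure_id[ranged]) note(id, "dropped_range")
      rec <- rec[!ranged, , drop = FALSE]
    }
  }

  has_parent <- !rec$is_mutant | rec$parent_id %in%
    rec$structure_id[!rec$is_mutant] | rec$parent_id == rec$structure_id
  for (id in rec$structure_id[!has_parent]) note(id, "dropped_orphan_mutant")
  rec <- rec[has_parent, , drop = FALSE]

  if (nrow(rec)) {
    # an existing dg column is authoritative (it may carry replicate
    # averages from an earlier pass); convert only where it is absent
    if (is.null(rec$dg)) rec$dg <- NA_real_
    need <- is.na(rec$dg)
    if (any(need)) {
      rec$dg[need] <- mapply(affinity_to_dg, rec$affinity_value[need],
                             rec$affinity_type[need], rec$unit[need],
                             rec$temperature[need])
    }
    key <- paste(rec$structure_id, rec$mutation, sep = "|")
    if (anyDuplicated(key)) {
      for (k in unique(key[duplicated(key)])) {
        note(rec$structure_id[key == k][1L], "averaged_replicates",
             sprintf("%d measurements", sum(key == k)))
      }
      agg <- tapply(rec$dg, key, mean)  # averaged on the dG scale
      rec <- rec[!duplicated(key), , drop = FALSE]
      rec$dg <- as.numeric(agg[paste(rec$structure_id, rec$mutation,
                                     sep = "|")])
    }
  } else {
    rec$dg <- numeric(0)
  }
  rownames(rec) <- NULL
  audit <- if (length(audit)) do.call(rbind, audit) else
    data.frame(structure_id = character(), code = character(),
               detail = character())
  list(kept = rec, audit = audit)
}

#' Global alignment percent identity (Needleman-Wunsch)
#'
#' Affine-gap global alignment (Gotoh three-state dynamic programming) with
#' BLOSUM62 scoring, gap opening 10 and gap extension 0.5 by default; a gap
#' of length L costs `open + L * extend`, matching the convention of
#' `Biostrings::pairwiseAlignment`. Identity is the number of identical
#' aligned positions divided by the full alignment length (gap columns
#' included in the denominator), times 100. Traceback ties resolve
#' diagonal > up > left. Non-amino-acid symbols map to `X` with a warning.
#'
#' @param seq_a,seq_b amino-acid sequences (character scalars).
#' @param substitution scoring matrix (default BLOSUM62 from Biostrings).
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @param details return the alignment strings as well?
#' @return Percent identity in `[0, 100]`, or when `details = TRUE` a list
#'   with `identity`, `score`, `alignment` (two aligned strings).
#' @export
nw_identity <- function(seq_a, seq_b, substitution = NULL,
                        gap_open = 10, gap_extend = 0.5, details = FALSE) {
  stopifnot(nchar(seq_a) > 0L, nchar(seq_b) > 0L)
  if (is.null(substitution)) substitution <- .blosum62()
  clean <- function(s) {
    v <- strsplit(toupper(s), "")[[1L]]
    bad <- !v %in% rownames(substitution)
    if (any(bad)) {
      warning("non-amino-acid symbol(s) mapped to X: ",
              paste(unique(v[bad]), collapse = ""))
      v[bad] <- "X"
    }
    v
  }
  a <- clean(seq_a); b <- clean(seq_b)
  n <- length(a); m <- length(b)
  neg <- -1e9
  # Gotoh: M = align, X = gap in b (consume a, "up"), Y = gap in a ("left")
  M <- matrix(neg, n + 1L, m + 1L); X <- M; Y <- M
  M[1L, 1L] <- 0
  X[-1L, 1L] <- -gap_open - gap_extend * seq_len(n)
  Y[1L, -1L] <- -gap_open - gap_extend * seq_len(m)
  tb_m <- matrix(0L, n + 1L, m + 1L)  # 1=M,2=X,3=Y origin of M cell
  tb_x <- matrix(0L, n + 1L, m + 1L)  # 1=open from M, 2=extend
  tb_y <- matrix(0L, n + 1L, m + 1L)
  tb_x[-1L, 1L] <- c(1L, rep(2L, n - 1L))
  tb_y[1L, -1L] <- c(1L, rep(2L, m - 1L))
  for (i in seq_len(n)) {
    si <- substitution[a[i], b]
    for (j in seq_len(m)) {
      # gap states first (they read row/column i, j-1 / i-1, j)
      xo <- M[i, j + 1L] - gap_open - gap_extend
      xe <- X[i, j + 1L] - gap_extend
      if (xo >= xe) { X[i + 1L, j + 1L] <- xo; tb_x[i + 1L, j + 1L] <- 1L }
      else { X[i + 1L, j + 1L] <- xe; tb_x[i + 1L, j + 1L] <- 2L }
      yo <- M[i + 1L, j] - gap_open - gap_extend
      ye <- Y[i + 1L, j] - gap_extend
      if (yo >= ye) { Y[i + 1L, j + 1L] <- yo; tb_y[i + 1L, j + 1L] <- 1L }
      else { Y[i + 1L, j + 1L] <- ye; tb_y[i + 1L, j + 1L] <- 2L }
      best <- M[i, j]; org <- 1L
      if (X[i, j] > best) { best <- X[i, j]; org <- 2L }
      if (Y[i, j] > best) { best <- Y[i, j]; org <- 3L }
      M[i + 1L, j + 1L] <- best + si[j]
      tb_m[i + 1L, j + 1L] <- org
    }
  }
  ends <- c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  state <- which.max(ends)  # ties: M (diagonal) preferred, then X (up)
  score <- ends[state]
  # traceback
  ai <- character(0); bi <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      ai <- c(a[i], ai); bi <- c(b[j], bi)
      state <- tb_m[i + 1L, j + 1L]
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      ai <- c(a[i], ai); bi <- c("-", bi)
      state <- if (tb_x[i + 1L, j + 1L] == 1L) 1L else 2L
      i <- i - 1L
    } else {
      ai <- c("-", ai); bi <- c(b[j], bi)
      state <- if (tb_y[i + 1L, j + 1L] == 1L) 1L else 3L
      j <- j - 1L
    }
  }
  ident <- 100 * sum(ai == bi & ai != "-") / length(ai)
  if (!details) return(ident)
  list(identity = ident, score = score,
       alignment = c(paste(ai, collapse = ""), paste(bi, collapse = "")))
}

.blosum62_cache <- new.env(parent = emptyenv())
.blosum62 <- function() {
  if (is.null(.blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum62_cache$m <- e$BLOSUM62
  }
  .blosum62_cache$m
}

#' Pairwise chain identity audit
#'
#' Evaluates [nw_identity()] on every unordered chain pair and reports the
#' pairs whose identity exceeds the threshold (used to enforce low
#' cross-chain redundancy, e.g. at most 25 percent).
#'
#' @param chains named character vector or list, chain id to sequence.
#' @param threshold percent identity ceiling (default 25).
#' @return List: `pass` (logical), `pairs` (data.frame of all pairs with
#'   identities), `violations` (subset above threshold).
#' @export
identity_audit <- function(chains, threshold = 25) {
  chains <- unlist(chains)
  stopifnot(length(chains) >= 2L)
  ids <- names(chains) %||% as.character(seq_along(chains))
  cmb <- utils::combn(length(chains), 2L)
  pairs <- data.frame(
    chain_1 = ids[cmb[1L, ]], chain_2 = ids[cmb[2L, ]],
    identity = vapply(seq_len(ncol(cmb)), function(k) {
      nw_identity(chains[[cmb[1L, k]]], chains[[cmb[2L, k]]])
    }, numeric(1)))
  violations <- pairs[pairs$identity > threshold, , drop = FALSE]
  list(pass = nrow(violations) == 0L, pairs = pairs, violations = violations)
}

#' Grouped cross-validation split plan
#'
#' Builds fold assignments where a mutant always travels with its parent
#' structure: the grouping key is `parent_id` (wild types group under their
#' own id). `"kfold"` ignores grouping; `"grouped_kfold"` distributes whole
#' groups over `k` folds balancing record counts; `"leave_one_protein_out"`
#' emits one fold per group.
#'
#' @param records data.frame with `structure_id` and (for grouped modes)
#'   `parent_id`/`is_mutant`, as from [curate_records()].
#' @param k number of folds (kfold modes).
#' @param mode `"kfold"`, `"grouped_kfold"`, or `"leave_one_protein_out"`.
#' @param seed integer seed for the shuffle.
#' @return Object of class `plaff_split_plan`: `folds` (list of integer row
#'   indices), `mode`, `seed`, `groups` (per-record group key).
#' @export
grouped_splits <- function(records, k = 10L,
                           mode = c("grouped_kfold", "kfold",
                                    "leave_one_protein_out"),
                           seed = 1L) {
  mode <- match.arg(mode)
  n <- nrow(records)
  stopifnot(n >= 2L)
  groups <- if (!is.null(records$parent_id)) {
    ifelse(is.na(records$parent_id) | records$parent_id == "",
           records$structure_id, records$parent_id)
  } else records$structure_id
  rng <- .seeded_rng(seed)

  if (mode == "kfold") {
    stopifnot(k >= 2L, k <= n)
    perm <- rng$sample(n)
    folds <- split(perm, rep_len(seq_len(k), n))
  } else {
    glist <- split(seq_len(n), groups)
    if (mode == "leave_one_protein_out") {
      folds <- glist[rng$sample(length(glist))]
    } else {
      stopifnot(k >= 2L)
      if (k > length(glist)) {
        stop("k = ", k, " exceeds the number of groups (", length(glist), ")")
      }
      ord <- rng$sample(length(glist))
      # largest-first greedy balance of record counts across folds
      sizes <- vapply(glist, length, integer(1))[ord]
      ord <- ord[order(-sizes)]
      load <- numeric(k)
      folds <- rep(list(integer(0)), k)
      for (gi in ord) {
        tgt <- which.min(load)
        folds[[tgt]] <- c(folds[[tgt]], glist[[gi]])
        load[tgt] <- load[tgt] + length(glist[[gi]])
      }
    }
  }
  names(folds) <- paste0("fold_", seq_along(folds))
  structure(list(folds = folds, mode = mode, seed = seed, k = length(folds),
                 groups = groups),
            class = "plaff_split_plan")
}

# local RNG that does not disturb the global .Random.seed
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    s
  })
  list(
    sample = function(n, size = n) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- sample.int(n, size)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, globalenv())
      out
    })
}

#' @export
print.plaff_split_plan <- function(x, ...) {
  sizes <- vapply(x$folds, length, integer(1))
  cat("Split plan (", x$mode, ", seed ", x$seed, "): ", length(x$folds),
      " folds, sizes ", paste(sizes, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Write/read a split plan as JSON text
#' @param plan a `plaff_split_plan`.
#' @param path file path.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(list(mode = plan$mode, seed = plan$seed,
                            folds = plan$folds), path, auto_unbox = TRUE)
  invisible(path)
}
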
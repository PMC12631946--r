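# Sequence-embedding block and feature-vector assembly.

#' One-letter sequence of a chain's residues
#'
#' Residues are read in (chain, resno, icode) order; non-standard residue
#' names map to `X`.
#'
#' @param atoms atom table (typically one partner).
#' @return Character scalar.
#' @export
chain_sequence <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = ":")
  first <- !duplicated(key)
  ord <- order(atoms$chain[first], atoms$resno[first], atoms$icode[first])
  rn <- atoms$resname[first][ord]
  letters1 <- AA1[rn]
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

#' Deterministic stub embedder
#'
#' A drop-in replacement for a protein-language-model embedder, for testing
#' and for pipelines where real embeddings are supplied externally. `kind =
#' "ones"` returns all-ones vectors; `"hash"` returns a fixed sinusoidal
#' code of the residue letter, deterministic and chunk-independent.
#'
#' @param base_width embedding width per residue (default 1280).
#' @param kind `"ones"` or `"hash"`.
#' @return A function `f(seq)` returning an `nchar(seq) x base_width`
#'   matrix.
#' @export
stub_embedder <- function(base_width = 1280L, kind = c("ones", "hash")) {
  kind <- match.arg(kind)
  force(base_width)
  function(seq) {
    n <- nchar(seq)
    stopifnot(n > 0L)
    if (kind == "ones") return(matrix(1, n, base_width))
    codes <- utf8ToInt(seq)
    t(vapply(codes, function(cc) sin(cc * seq_len(base_width) / 7),
             numeric(base_width)))
  }
}

#' File-backed per-residue embedder
#'
#' Reads a tab-separated table of precomputed per-residue embeddings: column
#' 1 the full sequence, column 2 the 1-based residue position, remaining
#' columns the embedding values. Lookups are keyed by the sequence string;
#' an unknown sequence is an error (no silent zeros).
#'
#' @param path TSV file (no header).
#' @return An embedder function `f(seq)`.
#' @export
file_embedder <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  function(seq) {
    rows <- tab[tab[[1L]] == seq, , drop = FALSE]
    if (nrow(rows) == 0L) stop("no embedding stored for sequence ", seq)
    rows <- rows[order(rows[[2L]]), , drop = FALSE]
    if (nrow(rows) != nchar(seq)) {
      stop("stored embedding has ", nrow(rows), " residues; sequence has ",
           nchar(seq))
    }
    as.matrix(rows[, -(1:2), drop = FALSE])
  }
}

#' Pooled sequence-embedding block
#'
#' Runs the embedder over both partner sequences (splitting sequences longer
#' than `max_len` into chunks and concatenating the per-residue rows back)
#' and mean-pools three segments: partner A residues, partner B residues,
#' and the union. With the default width 1280 the block is 3840-dimensional.
#'
#' @param embedder function returning an `n x base_width` matrix per
#'   sequence chunk (see [stub_embedder()], [file_embedder()]).
#' @param seq_a,seq_b partner sequences (non-empty; non-standard letters
#'   should already be `X`).
#' @param max_len maximum chunk length fed to the embedder (default 1022,
#'   a typical transformer input budget net of special tokens).
#' @return Object of class `plaff_embedding_block`: `values`
#'   (`3 * base_width`), `base_width`, `segments`.
#' @export
assemble_embedding_block <- function(embedder, seq_a, seq_b,
                                     max_len = 1022L) {
  stopifnot(is.function(embedder), nchar(seq_a) > 0L, nchar(seq_b) > 0L)
  embed_full <- function(seq) {
    if (nchar(seq) <= max_len) return(embedder(seq))
    starts <- seq(1L, nchar(seq), by = max_len)
    do.call(rbind, lapply(starts, function(s) {
      embedder(substr(seq, s, min(s + max_len - 1L, nchar(seq))))
    }))
  }
  ea <- embed_full(seq_a)
  eb <- embed_full(seq_b)
  if (ncol(ea) != ncol(eb)) stop("embedder width differs between partners")
  vals <- c(colMeans(ea), colMeans(eb), colMeans(rbind(ea, eb)))
  bw <- ncol(ea)
  names(vals) <- c(paste0("embA_", seq_len(bw)), paste0("embB_", seq_len(bw)),
                   paste0("embAB_", seq_len(bw)))
  structure(list(values = vals, base_width = bw,
                 segments = c("A", "B", "complex")),
            class = "plaff_embedding_block")
}

#' Assemble the full feature vector with a layout manifest
#'
#' Concatenates the blocks in fixed order -- topological, spectral,
#' auxiliary-A, auxiliary-B, embedding -- and records a manifest of
#' contiguous, non-overlapping index ranges covering the whole vector.
#' Missing blocks are simply skipped (the manifest reflects what is
#' present).
#'
#' @param topological a `plaff_topo_block` (or named numeric), optional.
#' @param spectral a `plaff_spectral_block`, optional.
#' @param aux_a,aux_b `plaff_aux_block`s, optional.
#' @param embedding a `plaff_embedding_block`, optional.
#' @param label optional binding free energy in kcal/mol.
#' @return Object of class `plaff_feature_vector`: `values`, `manifest`
#'   (`data.frame(block, start, end)`), `label`.
#' @export
assemble_feature_vector <- function(topological = NULL, spectral = NULL,
                                    aux_a = NULL, aux_b = NULL,
                                    embedding = NULL, label = NULL) {
  blocks <- list(topological = topological, spectral = spectral,
                 aux_a = aux_a, aux_b = aux_b, embedding = embedding)
  vals <- numeric(0)
  manifest <- list()
  for (nm in names(blocks)) {
    blk <- blocks[[nm]]
    if (is.null(blk)) next
    bv <- if (is.list(blk) && !is.null(blk$values)) blk$values else blk
    if (!is.numeric(bv)) stop("block ", nm, " is not numeric")
    manifest[[length(manifest) + 1L]] <-
      data.frame(block = nm, start = length(vals) + 1L,
                 end = length(vals) + length(bv))
    vals <- c(vals, bv)
  }
  manifest <- do.call(rbind, manifest)
  structure(list(values = vals, manifest = manifest, label = label),
            class = "plaff_feature_vector")
}

#' @export
print.plaff_feature_vector <- function(x, ...) {
  cat("Feature vector: ", length(x$values), " features in ",
      nrow(x$manifest), " blocks",
      if (!is.null(x$label)) paste0("; label ", format(x$label), " kcal/mol"),
      "\n", sep = "")
  print(x$manifest, row.names = FALSE)
  invisible(x)
}

#' Feature-group mask over a manifest
#'
#' Returns the indices of a named feature group, reproducing the ablation
#' groupings: `"auxiliary"` (both 74-slot partner blocks), `"topology"`
#' (barcode counts plus spectral statistics), `"esm"` (the pooled embedding
#' block), or `"all"`.
#'
#' @param fv a `plaff_feature_vector` (or its manifest).
#' @param group one of `"auxiliary"`, `"topology"`, `"esm"`, `"all"`.
#' @return Integer index vector into the feature vector.
#' @export
feature_mask <- function(fv, group = c("all", "auxiliary", "topology", "esm")) {
  group <- match.arg(group)
  manifest <- if (inherits(fv, "plaff_feature_vector")) fv$manifest else fv
  want <- switch(group,
                 all = manifest$block,
                 auxiliary = c("aux_a", "aux_b"),
                 topology = c("topological", "spectral"),
                 esm = "embedding")
  rows <- manifest[manifest$block %in% want, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no blocks present for group '", group, "'")
  unlist(lapply(seq_len(nrow(rows)), function(i) rows$start[i]:rows$end[i]),
         use.names = FALSE)
}

#' Full interface feature vector for one complex
#'
#' Convenience wrapper chaining interface extraction, the topological,
#' spectral and auxiliary blocks, and (optionally) the embedding block.
#'
#' @param pair a `plaff_partner_pair`.
#' @param cutoff_r interface cutoff, Angstrom.
#' @param element_list element-specific feature elements.
#' @param bins spectral/death bin thresholds.
#' @param embedder optional embedder; when `NULL` the embedding block is
#'   omitted.
#' @param label optional kcal/mol label.
#' @param ... passed to [binned_spectral_features()].
#' @return A `plaff_feature_vector`.
#' @export
complex_features <- function(pair, cutoff_r = 10.0,
                             element_list = c("C", "N", "O", "S"),
                             bins = 2:12, embedder = NULL, label = NULL,
                             ...) {
  region <- extract_interface(pair, cutoff_r, element_list)
  topo <- topological_feature_block(region, element_list,
                                    death_bins = c(0, bins),
                                    max_filtration = max(bins))
  spec <- binned_spectral_features(region, element_list, bins = bins, ...)
  aux_a <- assemble_auxiliary_block(pair, "A", region = region)
  aux_b <- assemble_auxiliary_block(pair, "B", region = region)
  emb <- if (!is.null(embedder)) {
    assemble_embedding_block(embedder,
                             chain_sequence(pair$partner_a),
                             chain_sequence(pair$partner_b))
  } else NULL
  assemble_feature_vector(topo, spec, aux_a, aux_b, emb, label = label)
}
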
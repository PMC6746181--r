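as_mutation_matrix <- function(x) {
  if (is.data.frame(x)) {
    if ("focus" %in% names(x)) {
      m <- as.matrix(x[setdiff(names(x), "focus")])
      rownames(m) <- x$focus
    } else {
      m <- as.matrix(x)
    }
  } else {
    m <- as.matrix(x)
  }
  if (is.null(rownames(m))) rownames(m) <- sprintf("focus_%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("mut_%03d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  if (nrow(m) < 2) abort("a focus-by-mutation matrix needs >= 2 foci")
  if (any(!m %in% c(0L, 1L))) abort("presence matrix must be binary")
  m
}

#' Simulate multiregion focus-by-mutation data with a known clone tree
#'
#' Draws a clone tree over `n_foci` tumor foci (a trunk edge shared by all
#' foci, then recursive splits), assigns each of `n_mutations` somatic
#' mutations to one tree edge (at least one on the trunk), and emits the
#' binary focus-by-mutation presence matrix implied by the tree -- a perfect
#' phylogeny with known trunk/branch/leaf labels for every mutation.
#'
#' @param n_foci number of sampled tumor foci (>= 2).
#' @param n_mutations number of somatic mutations (>= 1).
#' @param tree_shape `"random"`, `"linear"` (caterpillar) or `"balanced"`.
#' @param seed integer seed.
#' @return list of class `multiregion_sim`:
#'   * `matrix`: binary foci x mutations matrix;
#'   * `truth`: tibble with `mutation`, `class`, `foci` (list of carrying
#'     foci), `chrom`, `pos`, `ref`, `alt`;
#'   * `tree`: the truth `clone_tree`.
#' @examples
#' sim <- simulate_multiregion(4, 20, "random", seed = 1)
#' sim$truth
#' @export
simulate_multiregion <- function(n_foci, n_mutations,
                                 tree_shape = c("random", "linear",
                                                "balanced"),
                                 seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  if (n_foci < 2) abort("`n_foci` must be >= 2")
  if (n_mutations < 1) abort("`n_mutations` must be >= 1")
  withr::local_seed(seed)
  foci <- sprintf("focus_%d", seq_len(n_foci))

  edges <- list()
  split_set <- function(s) {
    edges[[length(edges) + 1L]] <<- s
    if (length(s) < 2) return(invisible())
    k <- switch(tree_shape,
                linear = 1L,
                balanced = length(s) %/% 2L,
                random = sample.int(length(s) - 1L, 1L))
    idx <- if (tree_shape == "random") sample(seq_along(s), k) else seq_len(k)
    split_set(s[idx])
    split_set(s[-idx])
  }
  split_set(seq_len(n_foci))

  edge_of <- c(1L, sample.int(length(edges), n_mutations - 1L,
                              replace = TRUE))
  mut <- sprintf("mut_%03d", seq_len(n_mutations))
  m <- matrix(0L, n_foci, n_mutations, dimnames = list(foci, mut))
  for (j in seq_len(n_mutations)) m[edges[[edge_of[j]]], j] <- 1L

  n_carry <- colSums(m)
  truth <- tibble(
    mutation = mut,
    class = dplyr::case_when(n_carry == n_foci ~ "trunk",
                             n_carry == 1L ~ "leaf",
                             TRUE ~ "branch"),
    foci = purrr::map(seq_len(n_mutations),
                      function(j) foci[m[, j] == 1L]),
    chrom = "chr1",
    pos = sort(sample.int(1e6, n_mutations)),
    ref = sample(DNA_BASES, n_mutations, replace = TRUE)
  )
  truth$alt <- vapply(truth$ref,
                      function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1), USE.NAMES = FALSE)
  structure(
    list(matrix = m, truth = truth, tree = build_tree(m)),
    class = "multiregion_sim"
  )
}

#' @export
print.multiregion_sim <- function(x, ...) {
  cat(sprintf("<multiregion_sim> %d foci x %d mutations (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(table(x$truth$class)[c("trunk", "branch", "leaf")],
                    c("trunk", "branch", "leaf"), collapse = ", ")))
  invisible(x)
}

#' Classify mutations as trunk, branch or leaf
#'
#' A mutation present in all sampled foci is truncal, one unique to a single
#' focus is a leaf, and anything in between is a branch of the tumor's clone
#' tree.
#'
#' @param matrix binary focus-by-mutation matrix (or data frame with a
#'   `focus` column).
#' @return tibble with `mutation`, `n_foci_present`, `n_foci`, `class`.
#' @examples
#' m <- rbind(f1 = c(a = 1, b = 1), f2 = c(a = 1, b = 0))
#' classify_clonality(m)
#' @export
classify_clonality <- function(matrix) {
  m <- as_mutation_matrix(matrix)
  n_carry <- colSums(m)
  if (any(n_carry == 0)) {
    abort("all-zero mutation column(s): every mutation must appear somewhere")
  }
  tibble(
    mutation = colnames(m),
    n_foci_present = as.integer(n_carry),
    n_foci = nrow(m),
    class = dplyr::case_when(n_carry == nrow(m) ~ "trunk",
                             n_carry == 1L ~ "leaf",
                             TRUE ~ "branch")
  )
}

columns_conflict <- function(m) {
  # pairs failing the three-gamete condition
  p <- ncol(m)
  out <- matrix(FALSE, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (j >= i) next
      a <- m[, i] == 1L; b <- m[, j] == 1L
      if (any(a & b) && any(a & !b) && any(!a & b)) {
        out[i, j] <- out[j, i] <- TRUE
      }
    }
  }
  out
}

#' Build a clone tree from a focus-by-mutation matrix
#'
#' If the matrix is conflict-free (no pair of mutations shows all three of
#' the 11/10/01 focus patterns) the unique perfect phylogeny is returned.
#' Otherwise columns are dropped greedily -- the column in the most
#' conflicts first, ties to the one carried by fewer foci -- until the
#' remainder is conflict-free; dropped mutations are reported.
#'
#' @param matrix binary focus-by-mutation matrix.
#' @return object of class `clone_tree`: list with
#'   * `nodes`: tibble `node_id`, `parent_id` (`NA` at the germline root),
#'     `n_foci`, `foci` (list), `mutations` (list);
#'   * `focus_nodes`: tibble mapping each focus to its node;
#'   * `dropped`: mutations removed to restore conflict-freeness.
#' @export
build_tree <- function(matrix) {
  m <- as_mutation_matrix(matrix)
  if (any(colSums(m) == 0)) {
    abort("all-zero mutation column(s): every mutation must appear somewhere")
  }
  dropped <- character(0)
  repeat {
    conf <- columns_conflict(m)
    n_conf <- rowSums(conf)
    if (all(n_conf == 0)) break
    worst <- which(n_conf == max(n_conf))
    worst <- worst[order(colSums(m)[worst], -worst)][1L]
    dropped <- c(dropped, colnames(m)[worst])
    m <- m[, -worst, drop = FALSE]
  }
  foci <- rownames(m)
  key <- apply(m, 2L, paste, collapse = "")
  root_key <- strrep("1", nrow(m))
  pat_keys <- unique(c(root_key, key))
  sizes <- vapply(pat_keys, function(k)
    sum(strsplit(k, "", fixed = TRUE)[[1L]] == "1"), integer(1))
  ord <- order(-sizes, pat_keys)
  pat_keys <- pat_keys[ord]
  sizes <- sizes[ord]
  pat_sets <- lapply(pat_keys, function(k)
    which(strsplit(k, "", fixed = TRUE)[[1L]] == "1"))
  n_nodes <- length(pat_keys)
  parent <- rep(NA_integer_, n_nodes)
  for (i in seq_len(n_nodes)[-1]) {
    sup <- which(vapply(seq_len(i - 1L), function(j)
      all(pat_sets[[i]] %in% pat_sets[[j]]), logical(1)))
    parent[i] <- sup[which.min(sizes[sup])]
  }
  nodes <- tibble(
    node_id = seq_len(n_nodes),
    parent_id = parent,
    n_foci = sizes,
    foci = lapply(pat_sets, function(s) foci[s]),
    mutations = lapply(pat_keys, function(k) colnames(m)[key == k])
  )
  focus_nodes <- tibble(
    focus = foci,
    node_id = vapply(seq_along(foci), function(f) {
      holding <- which(vapply(pat_sets, function(s) f %in% s, logical(1)))
      holding[which.min(sizes[holding])]
    }, integer(1))
  )
  structure(list(nodes = nodes, focus_nodes = focus_nodes,
                 dropped = dropped),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("<clone_tree> %d nodes over %d foci", nrow(x$nodes),
              nrow(x$focus_nodes)))
  if (length(x$dropped) > 0) {
    cat(sprintf(" (%d conflicting mutation(s) dropped)", length(x$dropped)))
  }
  cat("\n")
  invisible(x)
}

#' @rdname build_tree
#' @param x,object a `clone_tree`.
#' @param ... unused.
#' @method tidy clone_tree
#' @export
tidy.clone_tree <- function(x, ...) {
  dplyr::mutate(x$nodes,
                n_mutations = lengths(.data$mutations),
                foci = vapply(.data$foci, paste, character(1),
                              collapse = ","),
                mutations = vapply(.data$mutations, paste, character(1),
                                   collapse = ","))
}

#' @rdname build_tree
#' @method glance clone_tree
#' @export
glance.clone_tree <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes),
         n_foci = nrow(x$focus_nodes),
         n_mutations = sum(lengths(x$nodes$mutations)),
         n_dropped = length(x$dropped))
}

#' Serialise a clone tree to Newick plus a mutation sidecar
#'
#' Foci are the tips; edge lengths count the mutations on the edge above
#' each node. `write_clone_tree()` writes the Newick string and a JSON
#' sidecar listing the mutations attached to every edge.
#'
#' @param tree a `clone_tree`.
#' @return `as_newick()` returns the Newick string.
#' @export
as_newick <- function(tree) {
  nodes <- tree$nodes
  kids <- split(nodes$node_id[-1], nodes$parent_id[-1])
  tip_at <- split(tree$focus_nodes$focus, tree$focus_nodes$node_id)
  fmt <- function(id) {
    parts <- character(0)
    for (k in kids[[as.character(id)]] %||% integer(0)) parts <- c(parts, fmt(k))
    for (f in tip_at[[as.character(id)]] %||% character(0)) {
      parts <- c(parts, sprintf("%s:0", f))
    }
    label <- sprintf("n%d", id)
    blen <- length(nodes$mutations[[id]])
    if (length(parts) == 0) return(sprintf("%s:%d", label, blen))
    sprintf("(%s)%s:%d", paste(parts, collapse = ","), label, blen)
  }
  root <- nodes$node_id[is.na(nodes$parent_id)]
  paste0(fmt(root), ";")
}

#' @rdname as_newick
#' @param newick_path,json_path output paths.
#' @export
write_clone_tree <- function(tree, newick_path, json_path = NULL) {
  writeLines(as_newick(tree), newick_path)
  if (!is.null(json_path)) {
    payload <- purrr::map(seq_len(nrow(tree$nodes)), function(i) {
      list(node = sprintf("n%d", tree$nodes$node_id[i]),
           parent = ifelse(is.na(tree$nodes$parent_id[i]), NA,
                           sprintf("n%d", tree$nodes$parent_id[i])),
           foci = tree$nodes$foci[[i]],
           mutations = tree$nodes$mutations[[i]])
    })
    jsonlite::write_json(list(nodes = payload, dropped = tree$dropped),
                         json_path, auto_unbox = TRUE, null = "null")
  }
  invisible(newick_path)
}

#' Select mutations for a bespoke ctDNA assay
#'
#' Ranks candidate mutations by clone-tree position: truncal mutations
#' first (they mark every tumor cell), then branch mutations by descending
#' number of carrying foci (prevalence proxies clone size); leaves are
#' excluded by default. Ties break deterministically by genomic coordinate.
#'
#' @param matrix binary focus-by-mutation matrix.
#' @param k number of targets wanted (>= 1); fewer eligible mutations
#'   return all of them with a warning.
#' @param alleles optional tibble with `mutation`, `chrom`, `pos` (and any
#'   other allele columns) used for coordinate tie-breaks and carried into
#'   the output.
#' @param classes_allowed clonality classes eligible for selection.
#' @return ordered tibble of selected mutations with their class and focus
#'   count.
#' @export
select_targets <- function(matrix, k, alleles = NULL,
                           classes_allowed = c("trunk", "branch")) {
  if (k < 1) abort("`k` must be >= 1")
  cl <- classify_clonality(matrix)
  if (!is.null(alleles)) {
    cl <- dplyr::left_join(cl, alleles, by = "mutation",
                           suffix = c("", ".allele"))
  } else {
    cl$chrom <- "."
    cl$pos <- seq_len(nrow(cl))
  }
  eligible <- cl[cl$class %in% classes_allowed, , drop = FALSE]
  eligible <- dplyr::arrange(
    eligible,
    factor(.data$class, levels = c("trunk", "branch", "leaf")),
    dplyr::desc(.data$n_foci_present),
    .data$chrom, .data$pos
  )
  if (nrow(eligible) < k) {
    warn(sprintf("only %d eligible mutation(s) for k = %d", nrow(eligible), k))
  }
  utils::head(eligible, k)
}

#' Plot a clone tree
#'
#' @param object a `clone_tree`.
#' @param ... unused.
#' @return a ggplot: edges scaled by mutation count, foci as tips.
#' @method autoplot clone_tree
#' @export
autoplot.clone_tree <- function(object, ...) {
  nodes <- object$nodes
  kids <- split(nodes$node_id[-1], nodes$parent_id[-1])
  tip_at <- split(object$focus_nodes$focus, object$focus_nodes$node_id)
  depth <- rep(0, nrow(nodes))
  for (i in seq_len(nrow(nodes))[-1]) {
    depth[i] <- depth[nodes$parent_id[i]] + length(nodes$mutations[[i]])
  }
  tip_y <- stats::setNames(seq_len(nrow(object$focus_nodes)),
                           object$focus_nodes$focus)
  y <- rep(NA_real_, nrow(nodes))
  assign_y <- function(id) {
    ys <- c()
    for (k in kids[[as.character(id)]] %||% integer(0)) ys <- c(ys, assign_y(k))
    for (f in tip_at[[as.character(id)]] %||% character(0)) {
      ys <- c(ys, tip_y[[f]])
    }
    y[id] <<- mean(ys)
    y[id]
  }
  root <- nodes$node_id[is.na(nodes$parent_id)]
  assign_y(root)
  seg <- dplyr::filter(
    tibble(node_id = nodes$node_id, parent_id = nodes$parent_id,
           x = depth, y = y),
    !is.na(.data$parent_id))
  seg$xend <- depth[seg$parent_id]
  seg$yend <- y[seg$parent_id]
  tips <- tibble(
    focus = object$focus_nodes$focus,
    x = depth[object$focus_nodes$node_id],
    y = tip_y[object$focus_nodes$focus]
  )
  tipseg <- dplyr::mutate(tips, xend = .data$x,
                          yend = y[object$focus_nodes$node_id])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$xend, y = .data$yend,
                                       xend = .data$x, yend = .data$y)) +
    ggplot2::geom_segment(data = tipseg,
                          ggplot2::aes(x = .data$x, y = .data$yend,
                                       xend = .data$x, yend = .data$y),
                          linetype = "dotted") +
    ggplot2::geom_label(data = tips,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$focus)) +
    ggplot2::labs(x = "mutations from germline", y = NULL,
                  title = "Clone tree of tumor foci") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Write / read a focus-by-mutation matrix as TSV (foci rows)
#'
#' @param matrix binary focus-by-mutation matrix.
#' @param path file path.
#' @export
write_matrix_tsv <- function(matrix, path) {
  m <- as_mutation_matrix(matrix)
  df <- dplyr::bind_cols(tibble(focus = rownames(m)), as_tibble(m))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  as_mutation_matrix(df)
}
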
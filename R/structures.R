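#' Read divergent read-pair records from TSV
#'
#' Columns: `strain`, `chrom`, `left_start`, `left_end`, `right_start`,
#' `right_end`, `orientation` (`divergent` or `proper`), tab-separated with
#' header. Divergently oriented (outward-facing) pairs are the mapping
#' signature of a tandem-duplication junction.
#'
#' @param path Path to the TSV.
#' @return Data.frame of read-pair records.
#' @export
read_read_pairs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("strain", "chrom", "left_start", "left_end", "right_start",
            "right_end", "orientation")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("read-pair TSV missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$left_start > df$right_start))
    stop("left read must start before right read")
  df
}

#' Call tandem duplications from divergent read pairs
#'
#' A duplication is supported by three or more divergently oriented read
#' pairs whose anchors all lie within 25 kb of one another; the call span is
#' the outermost anchor extent of the group. Calls whose span overlaps any
#' divergent pair in the reference strain are dropped (such loci indicate
#' technical artifacts or reference mis-assembly, and the reference carries
#' none of the segregating duplications). Grouping is by coordinate order
#' per strain and chromosome: a sorted greedy scan adds a pair to the open
#' group while the group's outer span stays within `max_span`, so output is
#' invariant to input record order.
#'
#' @param pairs Data.frame of read-pair records (see [read_read_pairs()]);
#'   may contain several strains.
#' @param reference_pairs Optional data.frame of reference-strain records
#'   used for the exclusion filter.
#' @param min_pairs Minimum supporting divergent pairs per call (default 3).
#' @param max_span Maximum anchor span of a group in bp (default 25000).
#' @return Data.frame `strain`, `chrom`, `start`, `end`, `n_pairs`, sorted
#'   by strain, chromosome and start.
#' @export
call_duplications <- function(pairs, reference_pairs = NULL, min_pairs = 3,
                              max_span = 25000) {
  div <- pairs[pairs$orientation == "divergent", , drop = FALSE]
  empty <- data.frame(strain = character(), chrom = character(),
                      start = integer(), end = integer(), n_pairs = integer())
  if (!nrow(div)) return(empty)
  div <- div[order(div$strain, div$chrom, div$left_start, div$right_end), ]
  out <- list()
  for (key in unique(paste(div$strain, div$chrom, sep = "\r"))) {
    d <- div[paste(div$strain, div$chrom, sep = "\r") == key, , drop = FALSE]
    grp_start <- d$left_start[1L]; grp_end <- d$right_end[1L]; cnt <- 1L
    flush <- function(s, e, k) {
      if (k >= min_pairs)
        out[[length(out) + 1L]] <<- data.frame(
          strain = d$strain[1L], chrom = d$chrom[1L], start = s, end = e,
          n_pairs = k)
    }
    if (nrow(d) > 1L) for (i in 2:nrow(d)) {
      ns <- min(grp_start, d$left_start[i]); ne <- max(grp_end, d$right_end[i])
      if (ne - ns <= max_span) {
        grp_start <- ns; grp_end <- ne; cnt <- cnt + 1L
      } else {
        flush(grp_start, grp_end, cnt)
        grp_start <- d$left_start[i]; grp_end <- d$right_end[i]; cnt <- 1L
      }
    }
    flush(grp_start, grp_end, cnt)
  }
  calls <- if (length(out)) do.call(rbind, out) else empty
  if (!is.null(reference_pairs) && nrow(calls)) {
    rdiv <- reference_pairs[reference_pairs$orientation == "divergent", ,
                            drop = FALSE]
    if (nrow(rdiv)) {
      hit <- vapply(seq_len(nrow(calls)), function(i) {
        same <- rdiv$chrom == calls$chrom[i]
        any(same & rdiv$left_start <= calls$end[i] &
              rdiv$right_end >= calls$start[i])
      }, TRUE)
      calls <- calls[!hit, , drop = FALSE]
    }
  }
  calls <- calls[order(calls$strain, calls$chrom, calls$start), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Cluster duplication calls across strains
#'
#' Per-strain calls describing the same segregating duplication are merged
#' when both breakpoints agree within `dist` bp (start-to-start and
#' end-to-end, single linkage), the reading that keeps distinct nearby
#' events separate. The merged span is the maximum extent of divergent-read
#' anchors across all carrier strains, and the frequency is the number of
#' carrier strains.
#'
#' @param calls Data.frame from [call_duplications()] over all strains.
#' @param dist Breakpoint tolerance in bp (default 200).
#' @return Data.frame `chrom`, `start`, `end`, `n_pairs` (total supporting
#'   pairs), `strains` (comma-separated carriers), `frequency`.
#' @export
cluster_across_strains <- function(calls, dist = 200) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_pairs = integer(), strains = character(),
                      frequency = integer())
  if (!nrow(calls)) return(empty)
  calls <- calls[order(calls$chrom, calls$start, calls$end, calls$strain), ]
  n <- nrow(calls)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && calls$chrom[i] == calls$chrom[j] &&
        abs(calls$start[i] - calls$start[j]) <= dist &&
        abs(calls$end[i] - calls$end[j]) <= dist) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  merged <- lapply(split(seq_len(n), root), function(i) {
    data.frame(chrom = calls$chrom[i[1L]], start = min(calls$start[i]),
               end = max(calls$end[i]), n_pairs = sum(calls$n_pairs[i]),
               strains = paste(sort(unique(calls$strain[i])), collapse = ","),
               frequency = length(unique(calls$strain[i])))
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the structural consequences of a tandem duplication
#'
#' A tandem duplication of `[x, y]` inserts the copy head-to-tail, creating
#' the novel junction `y|x` (end of the segment joined to its start). The
#' consequence for each affected gene follows from where the breakpoints
#' fall:
#' * a full transcript (including both UTRs) inside the span is a
#'   **whole_gene** duplication;
#' * a breakpoint interior to a gene truncates it — the dup carries the
#'   gene's 5' or 3' fragment depending on strand and side;
#' * a 5' fragment joined at the junction to another gene's 3' fragment is a
#'   **chimera** (5' donor, 3' donor);
#' * a 5' fragment whose junction partner is intergenic sequence is
#'   **recruited_noncoding** (the copied promoter/5'UTR may activate
#'   previously untranscribed sequence — de novo gene origination);
#' * any other partial capture is a **gene_fragment**;
#' * a span overlapping no gene is **intergenic**.
#' One duplication can yield several records (one per affected gene, plus
#' one per chimera junction).
#'
#' @param dups Data.frame of duplication spans (`chrom`, `start`, `end`; a
#'   row id column `dup_id` is added if absent).
#' @param genes A [gene_model_set].
#' @return Data.frame `dup_id`, `chrom`, `start`, `end`, `class`, `gene_id`
#'   (comma-joined for chimeras), `portion` (`whole`, `5prime`, `3prime`,
#'   `internal` or `NA`), `junction` (`"y|x"` string).
#' @export
classify_structures <- function(dups, genes) {
  if (!("dup_id" %in% names(dups)))
    dups$dup_id <- paste0("dup", seq_len(nrow(dups)))
  rows <- list()
  add <- function(i, class, gene_id = NA_character_, portion = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      dup_id = dups$dup_id[i], chrom = dups$chrom[i], start = dups$start[i],
      end = dups$end[i], class = class, gene_id = gene_id, portion = portion,
      junction = paste0(dups$end[i], "|", dups$start[i]))
  }
  for (i in seq_len(nrow(dups))) {
    x <- dups$start[i]; y <- dups$end[i]; chrom <- dups$chrom[i]
    gs <- Filter(function(g) g$chrom == chrom && g$start <= y && g$end >= x,
                 genes$genes)
    if (!length(gs)) { add(i, "intergenic"); next }
    donors5 <- character(); donors3 <- character()
    strand5 <- character(); strand3 <- character()
    partial <- list()
    for (g in gs) {
      whole <- g$start >= x && g$end <= y
      if (whole) {
        if (!nrow(g$utr5) || !nrow(g$utr3))
          message("gene ", g$id,
                  ": UTRs not annotated; whole_gene decided on transcript span")
        add(i, "whole_gene", g$id, "whole")
        next
      }
      left_cut <- g$start < x               # gene crosses the dup start
      right_cut <- g$end > y                # gene crosses the dup end
      if (left_cut && right_cut) {          # duplication internal to the gene
        add(i, "gene_fragment", g$id, "internal")
        next
      }
      ## which portion of the gene does the copy carry?
      portion <- if (left_cut) {
        if (g$strand == "+") "3prime" else "5prime"
      } else {
        if (g$strand == "+") "5prime" else "3prime"
      }
      if (portion == "5prime") { donors5 <- c(donors5, g$id); strand5 <- c(strand5, g$strand) }
      else { donors3 <- c(donors3, g$id); strand3 <- c(strand3, g$strand) }
      partial[[g$id]] <- portion
    }
    used <- character()
    ## chimera: junction y|x fuses a captured 5' fragment to a captured 3'
    ## fragment of another gene on the same strand
    for (a in seq_along(donors5)) for (b in seq_along(donors3)) {
      if (strand5[a] == strand3[b] && donors5[a] != donors3[b]) {
        add(i, "chimera", paste(donors5[a], donors3[b], sep = ","))
        used <- c(used, donors5[a], donors3[b])
      }
    }
    for (gid in names(partial)) {
      if (gid %in% used) next
      if (partial[[gid]] == "5prime") {
        ## junction partner side: the other breakpoint of the junction y|x
        g <- genes$genes[[gid]]
        ## a plus-strand 5' fragment is cut at y and the junction y|x joins
        ## it to sequence starting at x; mirrored for minus strand
        partner <- if (g$strand == "+") x else y
        in_gene <- any(vapply(gs, function(h)
          h$id != gid && h$start <= partner && h$end >= partner, TRUE))
        add(i, if (in_gene) "gene_fragment" else "recruited_noncoding",
            gid, "5prime")
      } else {
        add(i, "gene_fragment", gid, partial[[gid]])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
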
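#' Chromosomes as sparse sets of derived mutations
#'
#' A chromosome is 2 or 3 blocks of `L` sites; each block is a sorted,
#' duplicate-free integer vector of derived-mutation positions in `[0, L)`.
#' Block 1 is the *original* block, block 2 the *single-copy* block, block 3
#' (present only on duplication carriers) the *duplicated* block. In
#' chromosome coordinates the blocks occupy `[0, L)`, `[L, 2L)`, `[2L, 3L)`.
#'
#' @param original,singlecopy,duplicated integer vectors of derived positions
#'   (0-based, within `[0, L)`); `duplicated = NULL` for a two-block
#'   chromosome.
#' @param L block length (used for validation only).
#' @return object of class `chromosome`: a list of sorted position vectors.
#' @export
#' @examples
#' chromosome(c(3, 10), integer(0), L = 100)
chromosome <- function(original = integer(0), singlecopy = integer(0),
                       duplicated = NULL, L = NULL) {
  blocks <- list(sort(unique(as.integer(original))),
                 sort(unique(as.integer(singlecopy))))
  if (!is.null(duplicated)) blocks[[3]] <- sort(unique(as.integer(duplicated)))
  if (!is.null(L)) {
    for (b in blocks) if (length(b) && (min(b) < 0 || max(b) >= L))
      stop("derived positions must lie in [0, L)")
  }
  structure(blocks, class = "chromosome")
}

n_blocks <- function(chrom) length(chrom)

#' @export
print.chromosome <- function(x, ...) {
  nm <- c("original", "singlecopy", "duplicated")[seq_along(x)]
  cat(sprintf("<chromosome> %d block(s)\n", length(x)))
  for (i in seq_along(x))
    cat(sprintf("  %-10s [%d]: %s\n", nm[i], length(x[[i]]),
                paste(head(x[[i]], 12L), collapse = " ")))
  invisible(x)
}

#' Polymorphism registry for the pseudo infinite-sites model
#'
#' New mutations may only arise at positions currently carrying no derived
#' allele in the relevant registry class. The single-copy block has its own
#' class; the original and duplicated blocks share a *joint* class, so a
#' variant segregating in either paralog blocks new mutations at that offset
#' in both.
#'
#' @param chroms list of `chromosome` objects (the materialized population).
#' @return list with integer vectors `singlecopy_poly` and `duplicate_poly`
#'   (class `polymorphism_registry`).
#' @export
build_registry <- function(chroms) {
  sc <- sort(unique(unlist(lapply(chroms, `[[`, 2L))))
  od <- sort(unique(unlist(lapply(chroms, function(ch) {
    if (n_blocks(ch) == 3L) c(ch[[1L]], ch[[3L]]) else ch[[1L]]
  }))))
  structure(list(singlecopy_poly = as.integer(sc), duplicate_poly = as.integer(od)),
            class = "polymorphism_registry")
}

registry_class_for_block <- function(block_id) {
  if (block_id == 2L) "singlecopy_poly" else "duplicate_poly"
}

#' Attempt one mutation on one block
#'
#' With probability `mu * L` a single new derived mutation is placed at a
#' position chosen uniformly among those *not* occupied in the block's
#' registry class (joint class for original/duplicated blocks). At most one
#' mutation per block per chromosome per generation; if every position is
#' occupied the event is skipped and counted, never raised.
#'
#' @param chrom a `chromosome`.
#' @param block_id 1 (original), 2 (single-copy) or 3 (duplicated).
#' @param registry a [build_registry()] result, kept consistent by the caller
#'   across a generation.
#' @param mu per-site per-generation mutation rate.
#' @param L block length.
#' @return list `(chrom, registry, mutated, skipped)`.
#' @export
sample_mutation <- function(chrom, block_id, registry, mu, L) {
  stopifnot(block_id >= 1L, block_id <= n_blocks(chrom))
  mutated <- FALSE; skipped <- FALSE
  if (runif(1) < mu * L) {
    cls <- registry_class_for_block(block_id)
    occupied <- registry[[cls]]
    if (length(occupied) >= L) {
      skipped <- TRUE
    } else {
      eligible <- setdiff(0:(L - 1L), occupied)
      pos <- eligible[sample.int(length(eligible), 1L)]
      chrom[[block_id]] <- sort(c(chrom[[block_id]], pos))
      registry[[cls]] <- sort(c(occupied, pos))
      mutated <- TRUE
    }
  }
  list(chrom = chrom, registry = registry, mutated = mutated, skipped = skipped)
}

#' Choose a crossover junction
#'
#' Called only for meioses already selected to recombine (the per-meiosis
#' probability `r` and the one-crossover-per-meiosis cap are handled
#' upstream). The junction is an integer site in chromosome coordinates; the
#' daughter inherits coordinates `<= junction` from the partner.
#'
#' Regions by case:
#' * equal-length 3-block meiosis — SCC: uniform on `[L, 2L)`; WRC: uniform on
#'   `[0, 3L)`; HSC: uniform over the hotspot union;
#' * mixed-length meiosis (2 vs 3 blocks) — uniform on the shared length
#'   `[0, 2L)` irrespective of model;
#' * equal-length 2-block meiosis — model region intersected with `[0, 2L)`,
#'   falling back to uniform on `[0, 2L)` if the intersection is empty.
#'
#' @param model `"SCC"`, `"WRC"` or `"HSC"`.
#' @param nb_parent,nb_partner block counts (2 or 3) of the two chromosomes.
#' @param hotspots hotspot interval matrix (HSC only).
#' @param L block length.
#' @return integer junction position.
#' @export
choose_crossover_junction <- function(model, nb_parent, nb_partner,
                                      hotspots = NULL, L) {
  stopifnot(nb_parent %in% c(2L, 3L), nb_partner %in% c(2L, 3L))
  if (nb_parent != nb_partner) return(sample_int_from(0, 2L * L))
  if (nb_parent == 3L) {
    switch(model,
      SCC = sample_int_from(L, 2L * L),
      WRC = sample_int_from(0, 3L * L),
      HSC = sample_from_intervals(hotspots))
  } else {
    region <- switch(model,
      SCC = matrix(c(L, 2L * L), ncol = 2),
      WRC = matrix(c(0, 2L * L), ncol = 2),
      HSC = clip_intervals(hotspots, 0, 2L * L))
    if (is.null(region) || nrow(region) == 0) region <- matrix(c(0, 2L * L), ncol = 2)
    sample_from_intervals(region)
  }
}

sample_int_from <- function(lo, hi) {       # uniform integer in [lo, hi)
  as.integer(lo + sample.int(hi - lo, 1L) - 1L)
}

clip_intervals <- function(iv, lo, hi) {
  if (is.null(iv)) return(NULL)
  s <- pmax(iv[, 1], lo); e <- pmin(iv[, 2], hi)
  keep <- s < e
  if (!any(keep)) return(NULL)
  cbind(s[keep], e[keep])
}

sample_from_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) stop("no interval to sample a junction from")
  len <- iv[, 2] - iv[, 1]
  u <- sample.int(sum(len), 1L) - 1L
  i <- findInterval(u, cumsum(c(0, len)), rightmost.closed = FALSE)
  as.integer(iv[i, 1] + (u - cumsum(c(0, len))[i]))
}

#' Recombine two chromosomes at a junction
#'
#' The daughter has the same number of blocks as its parent and carries the
#' partner's derived positions at chromosome coordinates `<= junction`
#' (junction included) and the parent's at coordinates `> junction`. A block
#' the partner lacks contributes nothing on the partner side. Inputs are not
#' modified.
#'
#' @param parent,partner `chromosome` objects.
#' @param junction integer chromosome coordinate.
#' @param L block length.
#' @return the daughter `chromosome`.
#' @export
recombine <- function(parent, partner, junction, L) {
  nbp <- n_blocks(parent); nbq <- n_blocks(partner)
  max_shared <- min(nbp, nbq) * L
  if (nbp != nbq) {
    if (junction < 0 || junction >= max_shared)
      stop("junction outside the shared length of a mixed-length meiosis")
  } else if (junction < 0 || junction >= nbp * L) {
    stop("junction outside the chromosomes")
  }
  blocks <- vector("list", nbp)
  for (b in seq_len(nbp)) {
    off <- (b - 1L) * L
    from_partner <- if (b <= nbq) partner[[b]][off + partner[[b]] <= junction] else integer(0)
    from_parent <- parent[[b]][off + parent[[b]] > junction]
    blocks[[b]] <- c(from_partner, from_parent)  # both sorted, disjoint ranges
  }
  structure(blocks, class = "chromosome")
}

#' Sample an IGC tract length
#'
#' Geometric law `P(l) = q (1-q)^(l-1)`, support `l >= 1`.
#'
#' @param q success parameter in `(0, 1]`. Under the default
#'   `tract_q_mode = "mean_lambda"`, `q = 1/lambda` so the mean is lambda.
#' @param n number of draws.
#' @return integer vector of tract lengths.
#' @export
sample_tract_length <- function(q, n = 1L) {
  if (q <= 0 || q > 1) stop("tract parameter q must lie in (0, 1]")
  if (q == 1) return(rep(1L, n))
  1L + rgeom(n, q)
}

#' Sample IGC initiation events for one chromosome-generation
#'
#' The number of events is Poisson with mean `2 L g` (the per-site initiation
#' probability `g` summed over the 2L duplicate sites); each event initiates
#' at a uniform position of a uniform duplicate block, picks a donor copy with
#' probability 1/2 each, and draws a tract length from [sample_tract_length()].
#' The realized tract extends `floor(l/2)` sites on both sides of the junction
#' and is truncated at the block edges.
#'
#' @param chrom a 3-block `chromosome`.
#' @param g per-site IGC initiation probability.
#' @param L block length.
#' @param q geometric tract parameter.
#' @return list of `igc_event` objects: `junction_block` ("original" or
#'   "duplicated"), `junction_pos`, `l`, `direction` ("orig_to_dup" or
#'   "dup_to_orig"), `tract = c(lo, hi)` (closed, clipped), `truncated`.
#' @export
sample_igc_initiations <- function(chrom, g, L, q) {
  if (n_blocks(chrom) != 3L) stop("IGC requires a 3-block chromosome")
  n_events <- rpois(1L, 2 * L * g)
  if (n_events == 0L) return(list())
  lapply(seq_len(n_events), function(i) {
    jglobal <- sample_int_from(0, 2L * L)
    jblock <- if (jglobal < L) "original" else "duplicated"
    jpos <- jglobal %% L
    l <- sample_tract_length(q)
    half <- l %/% 2L
    lo <- jpos - half; hi <- jpos + half
    truncated <- lo < 0L || hi > L - 1L
    structure(list(junction_block = jblock, junction_pos = jpos, l = l,
                   direction = if (runif(1) < 0.5) "orig_to_dup" else "dup_to_orig",
                   tract = c(max(0L, lo), min(L - 1L, hi)), truncated = truncated),
              class = "igc_event")
  })
}

#' Apply an IGC event to a chromosome
#'
#' Within the realized tract the receptor block's derived positions become
#' exactly the donor block's (a copy-paste: donor variants are imported,
#' receptor variants erased); outside the tract both blocks are unchanged and
#' the donor is never modified. Paralogous positions map by identity of
#' offsets. If `identity_threshold` is set and the paralog identity
#' `1 - d_s/L` falls below it, the event is skipped.
#'
#' @param chrom a 3-block `chromosome`.
#' @param event an `igc_event` from [sample_igc_initiations()].
#' @param identity_threshold optional fraction in `[0, 1]`; default off.
#' @param L block length (needed only when `identity_threshold` is set).
#' @return list `(chrom, applied)`.
#' @export
apply_igc <- function(chrom, event, identity_threshold = NULL, L = NULL) {
  if (n_blocks(chrom) != 3L) stop("IGC requires a 3-block chromosome")
  if (!is.null(identity_threshold)) {
    stopifnot(!is.null(L))
    d <- pairwise_diff(chrom[[1L]], chrom[[3L]])
    if (1 - d / L < identity_threshold) return(list(chrom = chrom, applied = FALSE))
  }
  donor_id <- if (event$direction == "orig_to_dup") 1L else 3L
  recv_id <- if (donor_id == 1L) 3L else 1L
  lo <- event$tract[1L]; hi <- event$tract[2L]
  donor <- chrom[[donor_id]]; recv <- chrom[[recv_id]]
  chrom[[recv_id]] <- c(recv[recv < lo], donor[donor >= lo & donor <= hi], recv[recv > hi])
  list(chrom = chrom, applied = TRUE)
}
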
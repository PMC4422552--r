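#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a phasing result
#'
#' @param x A `haplo_phasing`.
#' @param what `"blocks"` (default; one row per haplotype block) or
#'   `"sites"` (one row per phased site and haplotype).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.haplo_phasing <- function(x, what = c("blocks", "sites"), ...) {
  what <- match.arg(what)
  if (what == "blocks") return(x$blocks)
  purrr::map_dfr(seq_along(x$haplotype_blocks), function(b) {
    blk <- x$haplotype_blocks[[b]]
    hs <- blk$haps
    hom <- homozygous_sites(hs)
    tibble::tibble(block = b,
                   snp = rep(blk$snps, each = hs$K),
                   haplotype = rep(seq_len(hs$K), length(blk$snps)),
                   allele = as.integer(hs$alleles[cbind(
                     rep(seq_len(hs$K), length(blk$snps)),
                     rep(seq_along(blk$snps), each = hs$K))]),
                   homozygous = rep(hom, each = hs$K))
  })
}

#' One-row summary of a phasing result
#'
#' @param x A `haplo_phasing`.
#' @param ... Unused.
#' @return A tibble with one row: ploidy, mode, block count, phased SNPs,
#'   total MEC, largest-block share, convergence.
#' @export
glance.haplo_phasing <- function(x, ...) {
  n_phased <- sum(x$blocks$n_snps)
  tibble::tibble(K = x$K, mode = x$mode,
                 n_blocks = nrow(x$blocks),
                 n_snps = n_phased,
                 n_reads = sum(x$blocks$n_reads),
                 mec = sum(x$blocks$mec),
                 largest_block_frac =
                   if (n_phased) max(x$blocks$n_snps) / n_phased else NA_real_,
                 homozygous_sites = sum(vapply(
                   x$haplotype_blocks,
                   function(b) sum(homozygous_sites(b$haps)), 0)),
                 all_converged = all(x$blocks$converged))
}

#' Tidy a score report
#' @param x A `haplo_scores`.
#' @param ... Unused.
#' @return The per-block tibble (class stripped).
#' @export
tidy.haplo_scores <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x) != "overall"])
}

#' @rdname tidy.haplo_scores
#' @export
glance.haplo_scores <- function(x, ...) {
  ov <- attr(x, "overall")
  tibble::tibble(mec = ov$mec, switches = ov$switches,
                 opportunities = ov$opportunities, swer = ov$swer)
}

#' Plot solver diagnostics of a phasing result
#'
#' `type = "objective"` draws the coordinate-ascent objective trajectory of
#' each block's embedding (non-decreasing for diploid solves, noisy but
#' stabilizing for the Lagrangian scheme); `type = "blocks"` draws block
#' sizes against their MEC.
#'
#' @param object A `haplo_phasing`.
#' @param type `"objective"` or `"blocks"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.haplo_phasing <- function(object, type = c("objective", "blocks"),
                                   ...) {
  type <- match.arg(type)
  if (type == "objective") {
    traj <- purrr::map_dfr(seq_along(object$diagnostics), function(b) {
      d <- object$diagnostics[[b]]
      if (is.null(d) || !length(d$M_trace)) return(tibble::tibble())
      tibble::tibble(block = factor(b), sweep = seq_along(d$M_trace),
                     objective = d$M_trace)
    })
    return(ggplot2::ggplot(traj,
                           ggplot2::aes(.data$sweep, .data$objective,
                                        colour = .data$block)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "coordinate-ascent sweep",
                           y = "relaxation objective M",
                           colour = "block") +
             ggplot2::theme_minimal())
  }
  ggplot2::ggplot(object$blocks,
                  ggplot2::aes(.data$n_snps, .data$mec)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_reads), alpha = 0.7) +
    ggplot2::labs(x = "SNPs in block", y = "block MEC", size = "reads") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
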
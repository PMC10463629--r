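#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.assembly_graph <- function(x, ...) {
  x$edges
}

#' @export
glance.assembly_graph <- function(x, ...) {
  tibble(
    k = x$k,
    n_vertices = nrow(x$vertices),
    n_edges = nrow(x$edges),
    n_canonical_edges = sum(x$edges$edge <= x$edges$conjugate),
    total_bp = sum(x$edges$length),
    longest_edge_bp = max(x$edges$length)
  )
}

#' @export
tidy.deconv_result <- function(x, ...) {
  x$assignments
}

#' @export
glance.deconv_result <- function(x, ...) {
  enh <- enhanced_clouds(x)
  tibble(
    method = x$method,
    n_reads = nrow(x$assignments),
    n_clouds = nrow(x$clouds),
    n_enhanced_clouds = nrow(enh),
    n_disconnected_reads = sum(x$assignments$disconnected),
    avg_enhanced_size = mean(enh$size)
  )
}
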
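#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importClassesFrom IRanges RleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowRanges colData
#' @importFrom stats cor.test p.adjust pbinom dhyper rnbinom rbinom rpois
#'   rnorm runif setNames complete.cases t.test sd
#' @importFrom utils head tail
NULL

#' @export
setGeneric("methReads", function(x, ...) standardGeneric("methReads"))

#' @export
setGeneric("unmethReads", function(x, ...) standardGeneric("unmethReads"))

#' @export
setGeneric("totalReads", function(x, ...) standardGeneric("totalReads"))

#' @export
setGeneric("siteContext", function(x, ...) standardGeneric("siteContext"))

#' @export
setGeneric("sampleStage", function(x, ...) standardGeneric("sampleStage"))

#' @export
setGeneric("poolByStage", function(x, ...) standardGeneric("poolByStage"))

#' @export
setGeneric("depthRle", function(x, ...) standardGeneric("depthRle"))

#' @export
setGeneric("librarySize", function(x, ...) standardGeneric("librarySize"))
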
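// Large im2col workspaces are allocated and freed every training step; with
// glibc's default mmap threshold each one round-trips through mmap/munmap
// and is page-fault-zeroed on first touch.  Raising the threshold keeps the
// buffers on the heap freelist, where their reuse is nearly free.

#include <Rcpp.h>
#if defined(__GLIBC__)
#include <malloc.h>
#endif

// [[Rcpp::export]]
void cpp_tune_allocator() {
#if defined(__GLIBC__)
  mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
#endif
}
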
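// Channel-wise seizure tracking network: shared 1D CNN encoder over 1-s
// windows, shared bidirectional LSTM across windows, 2-class softmax head.
// Templated on the element type: float is the training/inference path,
// double backs the finite-difference gradient checks in the test suite.
//
// Layout (column-major):
//   instances  n = m*T + t  (channel-major), N = M*T
//   encoder input X0: S x N, one 1-s window per column
//   conv activations: 20 x K with K = L*N position-columns, L = S/2;
//     positions of one window are contiguous columns
//
// The implementation targets a memory-bandwidth-bound single-CPU setting:
// convolutions in layers 2/3 run as cache-blocked shifted GEMMs straight on
// the layer inputs (no im2col matrix is ever materialized), layer 1 is a
// fused conv+LeakyReLU+maxpool pass, batch-norm inputs are reconstructed
// algebraically in the backward pass instead of being cached, and the hot
// element-wise passes are compiled at -O3 so their fixed-width inner loops
// vectorize regardless of the site-wide optimization level.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>


using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const double BN_EPS = 1e-5;
static const uword BLOCK_COLS = 16384;   // ~1.3 MB per 20-row block

extern "C" {
void sgemm_(const char*, const char*, const int*, const int*, const int*,
            const float*, const float*, const int*, const float*, const int*,
            const float*, float*, const int*);
void dgemm_(const char*, const char*, const int*, const int*, const int*,
            const double*, const double*, const int*, const double*,
            const int*, const double*, double*, const int*);
}

#if defined(__GLIBC__)
#include <malloc.h>
#endif
#if defined(__unix__)
#include <unistd.h>
#include <sys/mman.h>
#endif

// Two allocator measures keep the repeated multi-hundred-MB activation
// buffers of training affordable on one CPU:
// (1) glibc is told to keep freed mid-size blocks on the heap instead of
//     returning pages to the kernel, so optimizer steps do not re-fault
//     them (glibc caps the mmap threshold at 32 MB, so this covers only
//     the smaller buffers);
// (2) the large per-recording activation matrices come from a process-wide
//     bump arena backed by transparent huge pages and reused across calls
//     -- through 4 KB pages the ~0.5 GB working set thrashes the TLB and
//     roughly doubles the cost of every pass.
// The arena is reset at the start of each forward pass, which invalidates
// any cache of an earlier forward; a generation counter turns a stale
// backward call into a clean error.  R is single-threaded, so one global
// arena suffices.

// [[Rcpp::init]]
void ictrack_tune_allocator(DllInfo* dll) {
  (void)dll;
#if defined(__GLIBC__)
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 1 << 30);
#endif
}

struct Arena {
  std::vector<std::pair<char*, size_t>> chunks;
  size_t cur = 0, off = 0;
  uint64_t gen = 0;
  void reset() { cur = 0; off = 0; ++gen; }
  void* alloc(size_t bytes) {
    bytes = (bytes + 63u) & ~(size_t)63u;
    for (;;) {
      if (cur < chunks.size()) {
        if (off + bytes <= chunks[cur].second) {
          void* p = chunks[cur].first + off;
          off += bytes;
          return p;
        }
        if (++cur < chunks.size()) { off = 0; continue; }
      }
      size_t sz = std::max(bytes, (size_t)256u << 20);
      sz = (sz + ((size_t)2 << 20) - 1) & ~(((size_t)2 << 20) - 1);
      char* p = nullptr;
#if defined(__unix__)
      p = (char*)mmap(nullptr, sz, PROT_READ | PROT_WRITE,
                      MAP_PRIVATE | MAP_ANONYMOUS, -1, 0);
      if (p == MAP_FAILED) p = nullptr;
#ifdef MADV_HUGEPAGE
      if (p) madvise(p, sz, MADV_HUGEPAGE);   // before first touch
#endif
#endif
      if (!p) p = (char*)std::malloc(sz);
      if (!p) Rcpp::stop("activation arena allocation failed");
      chunks.push_back(std::make_pair(p, sz));
      cur = chunks.size() - 1;
      off = 0;
    }
  }
};
static Arena g_arena;

// arma matrix view over arena memory (no copy, fixed size)
template <typename eT>
static Mat<eT> arena_mat(uword nr, uword nc) {
  return Mat<eT>((eT*)g_arena.alloc((size_t)nr * nc * sizeof(eT)), nr, nc,
                 false, true);
}
static Mat<unsigned char> arena_umat(uword nr, uword nc) {
  return Mat<unsigned char>(
      (unsigned char*)g_arena.alloc((size_t)nr * nc), nr, nc, false, true);
}

static inline void xgemm(char ta, char tb, int m, int n, int k, float alpha,
                         const float* A, int lda, const float* B, int ldb,
                         float beta, float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}
static inline void xgemm(char ta, char tb, int m, int n, int k, double alpha,
                         const double* A, int lda, const double* B, int ldb,
                         double beta, double* C, int ldc) {
  dgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

template <typename eT>
struct Params {
  Mat<eT> W1; Col<eT> b1; Col<eT> g1, be1, rm1, rv1;
  Mat<eT> W2; Col<eT> b2; Col<eT> g2, be2, rm2, rv2;
  Mat<eT> W3; Col<eT> b3; Col<eT> g3, be3, rm3, rv3;
  Mat<eT> Wif, Whf; Col<eT> bif;
  Mat<eT> Wib, Whb; Col<eT> bib;
  Mat<eT> Wo; Col<eT> bo;
  eT slope;
};

template <typename eT>
static Mat<eT> get_mat(const List& L, const char* nm) {
  Rcpp::NumericMatrix m = L[nm];
  Mat<eT> out(m.nrow(), m.ncol());
  const double* src = m.begin();
  eT* dst = out.memptr();
  for (uword i = 0; i < out.n_elem; ++i) dst[i] = (eT)src[i];
  return out;
}

template <typename eT>
static Col<eT> get_col(const List& L, const char* nm) {
  Rcpp::NumericVector v = L[nm];
  Col<eT> out(v.size());
  for (uword i = 0; i < out.n_elem; ++i) out[i] = (eT)v[i];
  return out;
}

template <typename eT>
static Params<eT> parse_params(const List& L, bool ablate) {
  Params<eT> p;
  p.W1 = get_mat<eT>(L, "conv1_w"); p.b1 = get_col<eT>(L, "conv1_b");
  p.g1 = get_col<eT>(L, "bn1_gamma"); p.be1 = get_col<eT>(L, "bn1_beta");
  p.rm1 = get_col<eT>(L, "bn1_mean"); p.rv1 = get_col<eT>(L, "bn1_var");
  p.W2 = get_mat<eT>(L, "conv2_w"); p.b2 = get_col<eT>(L, "conv2_b");
  p.g2 = get_col<eT>(L, "bn2_gamma"); p.be2 = get_col<eT>(L, "bn2_beta");
  p.rm2 = get_col<eT>(L, "bn2_mean"); p.rv2 = get_col<eT>(L, "bn2_var");
  p.W3 = get_mat<eT>(L, "conv3_w"); p.b3 = get_col<eT>(L, "conv3_b");
  p.g3 = get_col<eT>(L, "bn3_gamma"); p.be3 = get_col<eT>(L, "bn3_beta");
  p.rm3 = get_col<eT>(L, "bn3_mean"); p.rv3 = get_col<eT>(L, "bn3_var");
  if (!ablate) {
    p.Wif = get_mat<eT>(L, "lstm_f_wi"); p.Whf = get_mat<eT>(L, "lstm_f_wh");
    p.bif = get_col<eT>(L, "lstm_f_b");
    p.Wib = get_mat<eT>(L, "lstm_b_wi"); p.Whb = get_mat<eT>(L, "lstm_b_wh");
    p.bib = get_col<eT>(L, "lstm_b_b");
  }
  p.Wo = get_mat<eT>(L, "head_w"); p.bo = get_col<eT>(L, "head_b");
  p.slope = (eT)Rcpp::as<double>(L["leaky_slope"]);
  return p;
}

// per-feature affine (a, c) so that bn(x) = a*x + c
template <typename eT>
struct BnAff { Col<eT> a, c, mu, sg; };

template <typename eT>
struct Cache {
  uword M, T, S, L, N, K;      // K = L*N position columns
  bool ablate;
  uint64_t gen;                // arena generation this cache lives in
  Params<eT> par;
  // large activation matrices are non-owning views into the arena
  Mat<eT> X0;                  // S x N
  Mat<eT> P1pre;               // 20 x K  pooled LeakyReLU output, pre-BN
  Mat<unsigned char> pidx;     // which of the pooled pair won
  BnAff<eT> bn1, bn2, bn3;
  Mat<eT> O1;                  // 20 x K  layer-1 output
  Mat<eT> O2;                  // 20 x K  layer-2 output (O1 + bn2 path)
  Mat<eT> D3;                  // 20 x K  layer-3 batch-norm path output
  Mat<eT> H;                   // 20 x N  embeddings
  Mat<eT> Gf, Cf, Gb, Cb;      // LSTM gate/cell caches
  Mat<eT> O;                   // D x N   tracker outputs
  Mat<eT> Pr;                  // 2 x N   class probabilities

  Cache(uword M_, uword T_, uword S_)
      : M(M_), T(T_), S(S_), L(S_ / 2), N(M_ * T_), K((S_ / 2) * M_ * T_),
        ablate(false), gen(g_arena.gen),
        X0(arena_mat<eT>(S_, M_ * T_)),
        P1pre(arena_mat<eT>(20, (S_ / 2) * M_ * T_)),
        pidx(arena_umat(20, (S_ / 2) * M_ * T_)),
        O1(arena_mat<eT>(20, (S_ / 2) * M_ * T_)),
        O2(arena_mat<eT>(20, (S_ / 2) * M_ * T_)),
        D3(arena_mat<eT>(20, (S_ / 2) * M_ * T_)) {}
};

// fused conv1(k7,p3) + bias + LeakyReLU + maxpool(2) over all windows;
// accumulates batch-norm sums of the pooled values
template <typename eT>
__attribute__((noinline)) static void conv1_forward(const Mat<eT>& X0, uword S, uword L,
                                  const eT* W1, const eT* b1, eT slope,
                                  Mat<eT>& P1, Mat<unsigned char>& pidx,
                                  double* bsum, double* bsq) {
  const uword N = X0.n_cols;
  for (uword n = 0; n < N; ++n) {
    const eT* x = X0.colptr(n);
    eT* P = P1.colptr(n * L);
    unsigned char* Q = pidx.colptr(n * L);
    eT v0[20], v1[20];
    for (uword s2 = 0; s2 < L; ++s2) {
      for (uword half = 0; half < 2; ++half) {
        const int pos = (int)(2 * s2 + half);
        eT* acc = half ? v1 : v0;
        for (int r = 0; r < 20; ++r) acc[r] = b1[r];
        const int k0 = std::max(0, 3 - pos);
        const int k1 = std::min(6, (int)S - 1 + 3 - pos);
        for (int k = k0; k <= k1; ++k) {
          const eT xv = x[pos - 3 + k];
          const eT* wk = W1 + 20 * k;
          for (int r = 0; r < 20; ++r) acc[r] += wk[r] * xv;
        }
        for (int r = 0; r < 20; ++r)
          acc[r] = acc[r] > eT(0) ? acc[r] : acc[r] * slope;
      }
      eT* d = P + 20 * s2;
      unsigned char* q = Q + 20 * s2;
      for (int r = 0; r < 20; ++r) {
        if (v0[r] >= v1[r]) { d[r] = v0[r]; q[r] = 0; }
        else                { d[r] = v1[r]; q[r] = 1; }
        bsum[r] += d[r];
        bsq[r] += (double)d[r] * d[r];
      }
    }
  }
}

// Y = a * X + c, row-wise affine
template <typename eT>
__attribute__((noinline)) static void affine_pass(const Mat<eT>& X, Mat<eT>& Y, const eT* a,
                                const eT* c) {
  const uword K = X.n_cols;
  for (uword j = 0; j < K; ++j) {
    const eT* x = X.colptr(j);
    eT* y = Y.colptr(j);
    for (int r = 0; r < 20; ++r) y[r] = a[r] * x[r] + c[r];
  }
}

// in place: A <- LeakyReLU(A + b); accumulates per-row sums/squares
template <typename eT>
__attribute__((noinline)) static void bias_leaky_stats(Mat<eT>& A, const eT* b, eT slope,
                                     double* bsum, double* bsq) {
  const uword K = A.n_cols;
  for (uword j0 = 0; j0 < K; j0 += 2048) {
    const uword j1 = std::min(j0 + 2048, K);
    eT ps[20], pq[20];
    for (int r = 0; r < 20; ++r) { ps[r] = 0; pq[r] = 0; }
    for (uword j = j0; j < j1; ++j) {
      eT* a = A.colptr(j);
      for (int r = 0; r < 20; ++r) {
        eT v = a[r] + b[r];
        v = v > eT(0) ? v : v * slope;
        a[r] = v;
        ps[r] += v;
        pq[r] += v * v;
      }
    }
    for (int r = 0; r < 20; ++r) { bsum[r] += ps[r]; bsq[r] += pq[r]; }
  }
}

// O2 = O1 + a*A + c (batch-norm apply plus residual)
template <typename eT>
__attribute__((noinline)) static void bn_res_pass(const Mat<eT>& A, const Mat<eT>& O1,
                                Mat<eT>& O2, const eT* a, const eT* c) {
  const uword K = A.n_cols;
  for (uword j = 0; j < K; ++j) {
    const eT* av = A.colptr(j);
    const eT* o1 = O1.colptr(j);
    eT* y = O2.colptr(j);
    for (int r = 0; r < 20; ++r) y[r] = o1[r] + a[r] * av[r] + c[r];
  }
}

// in place D3 <- a*D3 + c; H[:, n] = mean over the window of (D3 + O2)
template <typename eT>
__attribute__((noinline)) static void bn_gap_pass(Mat<eT>& D3, const Mat<eT>& O2, Mat<eT>& H,
                                const eT* a, const eT* c, uword N, uword L) {
  for (uword n = 0; n < N; ++n) {
    eT h[20] = {0};
    for (uword s2 = 0; s2 < L; ++s2) {
      const uword j = n * L + s2;
      eT* d = D3.colptr(j);
      const eT* o2 = O2.colptr(j);
      for (int r = 0; r < 20; ++r) {
        d[r] = a[r] * d[r] + c[r];
        h[r] += d[r] + o2[r];
      }
    }
    eT* hc = H.colptr(n);
    for (int r = 0; r < 20; ++r) hc[r] = h[r] / (eT)L;
  }
}

template <typename eT>
static BnAff<eT> bn_affine_train(const double* bsum, const double* bsq,
                                 uword K, const Col<eT>& g,
                                 const Col<eT>& be) {
  BnAff<eT> o;
  o.a.set_size(20); o.c.set_size(20); o.mu.set_size(20); o.sg.set_size(20);
  for (int r = 0; r < 20; ++r) {
    const double m = bsum[r] / K;
    const double v = std::max(bsq[r] / K - m * m, 0.0);
    o.mu[r] = (eT)m;
    o.sg[r] = (eT)std::sqrt(v + BN_EPS);
    o.a[r] = g[r] / o.sg[r];
    o.c[r] = be[r] - o.a[r] * o.mu[r];
  }
  return o;
}

template <typename eT>
static BnAff<eT> bn_affine_infer(const Col<eT>& rm, const Col<eT>& rv,
                                 const Col<eT>& g, const Col<eT>& be) {
  BnAff<eT> o;
  o.a.set_size(20); o.c.set_size(20); o.mu = rm;
  o.sg.set_size(20);
  for (int r = 0; r < 20; ++r) {
    o.sg[r] = (eT)std::sqrt((double)rv[r] + BN_EPS);
    o.a[r] = g[r] / o.sg[r];
    o.c[r] = be[r] - o.a[r] * rm[r];
  }
  return o;
}

// shifted-GEMM convolution (kernel 3, pad 1, per-window padding):
// A[:, j] = Wl P[:, j-1] + Wm P[:, j] + Wr P[:, j+1] within each window.
// W is 20 x 60 = [Wl | Wm | Wr]; runs in cache-sized column blocks, then
// per-window edge corrections remove the cross-window terms.
template <typename eT>
static void conv3_forward(const Mat<eT>& W, const Mat<eT>& P, uword L,
                          Mat<eT>& A) {
  const uword K = P.n_cols;      // A must be pre-sized to 20 x K
  const eT* Wl = W.colptr(0);
  const eT* Wm = W.colptr(20);
  const eT* Wr = W.colptr(40);
  for (uword j0 = 0; j0 < K; j0 += BLOCK_COLS) {
    const uword j1 = std::min(j0 + BLOCK_COLS, K);
    const int nb = (int)(j1 - j0);
    xgemm('N', 'N', 20, nb, 20, eT(1), Wm, 20, P.colptr(j0), 20, eT(0),
          A.colptr(j0), 20);
    const uword lo = std::max<uword>(j0, 1);
    if (lo < j1)
      xgemm('N', 'N', 20, (int)(j1 - lo), 20, eT(1), Wl, 20,
            P.colptr(lo - 1), 20, eT(1), A.colptr(lo), 20);
    const uword hi = std::min<uword>(j1, K - 1);
    if (j0 < hi)
      xgemm('N', 'N', 20, (int)(hi - j0), 20, eT(1), Wr, 20,
            P.colptr(j0 + 1), 20, eT(1), A.colptr(j0), 20);
  }
  for (uword j = 0; j < K; ++j) {               // cross-window corrections
    if (j % L == 0 && j > 0) {
      const eT* src = P.colptr(j - 1);
      eT* d = A.colptr(j);
      for (int r = 0; r < 20; ++r) {
        eT s = 0;
        for (int q = 0; q < 20; ++q) s += Wl[r + 20 * q] * src[q];
        d[r] -= s;
      }
    }
    if (j % L == L - 1 && j + 1 < K) {
      const eT* src = P.colptr(j + 1);
      eT* d = A.colptr(j);
      for (int r = 0; r < 20; ++r) {
        eT s = 0;
        for (int q = 0; q < 20; ++q) s += Wr[r + 20 * q] * src[q];
        d[r] -= s;
      }
    }
  }
}

// transpose pass of conv3_forward: dP[:, j] = Wm' dA[:, j] + Wl' dA[:, j+1]
// + Wr' dA[:, j-1] within each window (overwrites dP).  The residual and
// GAP gradient additions are fused into the block loop while the block is
// cache-hot: dP += residual (full matrix) and dP[:, j] += gap[:, j / L]
// (window-constant broadcast), either may be null.
template <typename eT>
static void conv3_backward_data(const Mat<eT>& W, const Mat<eT>& dA, uword L,
                                Mat<eT>& dP, const Mat<eT>* residual,
                                const Mat<eT>* gap) {
  const uword K = dA.n_cols;     // dP must be pre-sized to 20 x K
  const eT* Wl = W.colptr(0);
  const eT* Wm = W.colptr(20);
  const eT* Wr = W.colptr(40);
  for (uword j0 = 0; j0 < K; j0 += BLOCK_COLS) {
    const uword j1 = std::min(j0 + BLOCK_COLS, K);
    const int nb = (int)(j1 - j0);
    xgemm('T', 'N', 20, nb, 20, eT(1), Wm, 20, dA.colptr(j0), 20, eT(0),
          dP.colptr(j0), 20);
    const uword hi = std::min<uword>(j1, K - 1);
    if (j0 < hi)    // in[:, j] feeds out[:, j+1] through Wl
      xgemm('T', 'N', 20, (int)(hi - j0), 20, eT(1), Wl, 20,
            dA.colptr(j0 + 1), 20, eT(1), dP.colptr(j0), 20);
    const uword lo = std::max<uword>(j0, 1);
    if (lo < j1)    // in[:, j] feeds out[:, j-1] through Wr
      xgemm('T', 'N', 20, (int)(j1 - lo), 20, eT(1), Wr, 20,
            dA.colptr(lo - 1), 20, eT(1), dP.colptr(lo), 20);
    for (uword j = j0; j < j1; ++j) {
      eT* d = dP.colptr(j);
      if (j % L == L - 1 && j + 1 < K) {
        const eT* src = dA.colptr(j + 1);
        for (int r = 0; r < 20; ++r) {
          eT s = 0;
          for (int q = 0; q < 20; ++q) s += Wl[q + 20 * r] * src[q];
          d[r] -= s;
        }
      }
      if (j % L == 0 && j > 0) {
        const eT* src = dA.colptr(j - 1);
        for (int r = 0; r < 20; ++r) {
          eT s = 0;
          for (int q = 0; q < 20; ++q) s += Wr[q + 20 * r] * src[q];
          d[r] -= s;
        }
      }
      if (residual) {
        const eT* a = residual->colptr(j);
        for (int r = 0; r < 20; ++r) d[r] += a[r];
      }
      if (gap) {
        const eT* g = gap->colptr(j / L);
        for (int r = 0; r < 20; ++r) d[r] += g[r];
      }
    }
  }
}

// weight gradient of the shifted convolution: blocked full-range GEMMs
// minus the per-window boundary outer products that cross window edges
template <typename eT>
static void conv3_backward_weights(const Mat<eT>& dA, const Mat<eT>& P,
                                   uword L, Mat<eT>& dW, Col<eT>& db) {
  const uword K = dA.n_cols;
  dW.zeros(20, 60);
  for (uword j0 = 0; j0 < K; j0 += BLOCK_COLS) {
    const uword j1 = std::min(j0 + BLOCK_COLS, K);
    xgemm('N', 'T', 20, 20, (int)(j1 - j0), eT(1), dA.colptr(j0), 20,
          P.colptr(j0), 20, eT(1), dW.colptr(20), 20);
    const uword lo = std::max<uword>(j0, 1);
    if (lo < j1)          // left tap: sum_j dA[:, j] P[:, j-1]'
      xgemm('N', 'T', 20, 20, (int)(j1 - lo), eT(1), dA.colptr(lo), 20,
            P.colptr(lo - 1), 20, eT(1), dW.colptr(0), 20);
    const uword hi = std::min<uword>(j1, K - 1);
    if (j0 < hi)          // right tap: sum_j dA[:, j] P[:, j+1]'
      xgemm('N', 'T', 20, 20, (int)(hi - j0), eT(1), dA.colptr(j0), 20,
            P.colptr(j0 + 1), 20, eT(1), dW.colptr(40), 20);
  }
  eT* dWl = dW.colptr(0);
  eT* dWr = dW.colptr(40);
  for (uword b = 0; b < K; b += L) {            // window starts
    if (b > 0) {                                // drop dA[:, b] P[:, b-1]'
      const eT* da = dA.colptr(b);
      const eT* pp = P.colptr(b - 1);
      for (int q = 0; q < 20; ++q)
        for (int r = 0; r < 20; ++r) dWl[r + 20 * q] -= da[r] * pp[q];
    }
    const uword e = b + L - 1;                  // window end
    if (e + 1 < K) {                            // drop dA[:, e] P[:, e+1]'
      const eT* da = dA.colptr(e);
      const eT* pp = P.colptr(e + 1);
      for (int q = 0; q < 20; ++q)
        for (int r = 0; r < 20; ++r) dWr[r + 20 * q] -= da[r] * pp[q];
    }
  }
  db = sum(dA, 1);
}

// fused reductions for the batch-norm backward: per feature,
// sd = sum dY, sdx = sum dY * xh with xh = (Y2 - Y1 - be)/g (Y1 optional)
template <typename eT>
__attribute__((noinline)) static void bn_reduce(const Mat<eT>& dY, const Mat<eT>& Y2,
                              const Mat<eT>* Y1, const eT* be, const eT* ig,
                              double* sd, double* sdx) {
  const uword K = dY.n_cols;
  for (uword j0 = 0; j0 < K; j0 += 2048) {
    const uword j1 = std::min(j0 + 2048, K);
    eT ps[20], px[20];
    for (int r = 0; r < 20; ++r) { ps[r] = 0; px[r] = 0; }
    for (uword j = j0; j < j1; ++j) {
      const eT* d = dY.colptr(j);
      const eT* y2 = Y2.colptr(j);
      if (Y1) {
        const eT* y1 = Y1->colptr(j);
        for (int r = 0; r < 20; ++r) {
          ps[r] += d[r];
          px[r] += d[r] * ((y2[r] - y1[r] - be[r]) * ig[r]);
        }
      } else {
        for (int r = 0; r < 20; ++r) {
          ps[r] += d[r];
          px[r] += d[r] * ((y2[r] - be[r]) * ig[r]);
        }
      }
    }
    for (int r = 0; r < 20; ++r) { sd[r] += ps[r]; sdx[r] += px[r]; }
  }
}

// batch-norm backward apply + LeakyReLU mask, writing dA:
// dA = gos*(dY - m1 - xh*m2) masked by sign(xh*sg + mu)
template <typename eT>
__attribute__((noinline)) static void bn_apply_grad(const Mat<eT>& dY, const Mat<eT>& Y2,
                                  const Mat<eT>* Y1, const eT* be,
                                  const eT* ig, const eT* gos, const eT* m1,
                                  const eT* m2, const eT* sg, const eT* mu,
                                  eT slope, Mat<eT>& dA) {
  const uword K = dY.n_cols;
  for (uword j = 0; j < K; ++j) {
    const eT* d = dY.colptr(j);
    const eT* y2 = Y2.colptr(j);
    const eT* y1 = Y1 ? Y1->colptr(j) : nullptr;
    eT* o = dA.colptr(j);
    for (int r = 0; r < 20; ++r) {
      const eT xh = ((y1 ? y2[r] - y1[r] : y2[r]) - be[r]) * ig[r];
      eT v = gos[r] * (d[r] - m1[r] - xh * m2[r]);
      const eT pre = xh * sg[r] + mu[r];
      o[r] = pre > eT(0) ? v : v * slope;
    }
  }
}

// layer-3 variants where dY is the window-constant GAP gradient dH[:, n]
template <typename eT>
__attribute__((noinline)) static void bn_reduce_gap(const Mat<eT>& dH, const Mat<eT>& D3,
                                  const eT* be, const eT* ig, uword N,
                                  uword L, double* sdx) {
  for (uword n = 0; n < N; ++n) {
    const eT* g = dH.colptr(n);
    eT px[20] = {0};
    for (uword s2 = 0; s2 < L; ++s2) {
      const eT* d3 = D3.colptr(n * L + s2);
      for (int r = 0; r < 20; ++r) px[r] += (d3[r] - be[r]) * ig[r];
    }
    for (int r = 0; r < 20; ++r) sdx[r] += (double)g[r] * px[r];
  }
}

template <typename eT>
__attribute__((noinline)) static void bn_apply_grad_gap(const Mat<eT>& dH, const Mat<eT>& D3,
                                      const eT* be, const eT* ig,
                                      const eT* gos, const eT* m1,
                                      const eT* m2, const eT* sg,
                                      const eT* mu, eT slope, uword N,
                                      uword L, Mat<eT>& dA) {
  for (uword n = 0; n < N; ++n) {
    const eT* g = dH.colptr(n);
    for (uword s2 = 0; s2 < L; ++s2) {
      const uword j = n * L + s2;
      const eT* d3 = D3.colptr(j);
      eT* o = dA.colptr(j);
      for (int r = 0; r < 20; ++r) {
        const eT xh = (d3[r] - be[r]) * ig[r];
        eT v = gos[r] * (g[r] - m1[r] - xh * m2[r]);
        const eT pre = xh * sg[r] + mu[r];
        o[r] = pre > eT(0) ? v : v * slope;
      }
    }
  }
}

// fused layer-1 backward: batch-norm grad -> LeakyReLU mask -> unpool ->
// conv1 weight/bias gradients (the raw input needs no gradient)
template <typename eT>
__attribute__((noinline)) static void conv1_backward(const Mat<eT>& dO1, const Mat<eT>& O1,
                                   const Mat<eT>& P1, const
                                   Mat<unsigned char>& pidx,
                                   const Mat<eT>& X0, uword S, uword L,
                                   const eT* be, const eT* ig, const eT* gos,
                                   const eT* m1, const eT* m2, const eT* sg,
                                   const eT* mu, eT slope, double* w1acc,
                                   double* b1acc) {
  const uword N = X0.n_cols;
  for (uword n = 0; n < N; ++n) {
    const eT* x = X0.colptr(n);
    for (uword s2 = 0; s2 < L; ++s2) {
      const uword j = n * L + s2;
      const eT* d = dO1.colptr(j);
      const eT* o1 = O1.colptr(j);
      const eT* v = P1.colptr(j);
      const unsigned char* q = pidx.colptr(j);
      for (int r = 0; r < 20; ++r) {
        const eT xh = (o1[r] - be[r]) * ig[r];
        eT gr = gos[r] * (d[r] - m1[r] - xh * m2[r]);
        gr = v[r] > eT(0) ? gr : gr * slope;
        const int pos = (int)(2 * s2 + q[r]);
        b1acc[r] += gr;
        const int k0 = std::max(0, 3 - pos);
        const int k1 = std::min(6, (int)S - 1 + 3 - pos);
        for (int k = k0; k <= k1; ++k)
          w1acc[r + 20 * k] += (double)gr * x[pos - 3 + k];
      }
    }
  }
}

static inline double sigmoid_d(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// one LSTM direction over all channels at once; writes h into O rows r0..r0+39
template <typename eT>
static void lstm_dir(const Mat<eT>& Wi, const Mat<eT>& Wh, const Col<eT>& b,
                     const Mat<eT>& H, uword M, uword T, bool fwd,
                     Mat<eT>& G, Mat<eT>& C, Mat<eT>& O, uword r0,
                     bool keep_cache) {
  const uword N = M * T;
  Mat<eT> Pin = Wi * H;
  Pin.each_col() += b;
  if (keep_cache) { G.set_size(160, N); C.set_size(40, N); }
  Mat<eT> h(40, M, fill::zeros), c(40, M, fill::zeros), g(160, M);
  for (uword step = 0; step < T; ++step) {
    const uword t = fwd ? step : T - 1 - step;
    for (uword m = 0; m < M; ++m)
      std::memcpy(g.colptr(m), Pin.colptr(m * T + t), 160 * sizeof(eT));
    g += Wh * h;
    for (uword m = 0; m < M; ++m) {
      eT* gc = g.colptr(m);
      eT* cc = c.colptr(m);
      eT* hc = h.colptr(m);
      for (int r = 0; r < 40; ++r) {
        const double i_ = sigmoid_d(gc[r]);
        const double f_ = sigmoid_d(gc[40 + r]);
        const double z_ = std::tanh((double)gc[80 + r]);
        const double o_ = sigmoid_d(gc[120 + r]);
        const double cn = f_ * cc[r] + i_ * z_;
        gc[r] = (eT)i_; gc[40 + r] = (eT)f_;
        gc[80 + r] = (eT)z_; gc[120 + r] = (eT)o_;
        cc[r] = (eT)cn;
        hc[r] = (eT)(o_ * std::tanh(cn));
      }
      const uword n = m * T + t;
      if (keep_cache) {
        std::memcpy(G.colptr(n), gc, 160 * sizeof(eT));
        std::memcpy(C.colptr(n), cc, 40 * sizeof(eT));
      }
      std::memcpy(O.colptr(n) + r0, hc, 40 * sizeof(eT));
    }
  }
}

template <typename eT>
static void lstm_dir_backward(const Mat<eT>& Wi, const Mat<eT>& Wh,
                              const Mat<eT>& H, const Mat<eT>& G,
                              const Mat<eT>& C, const Mat<eT>& O, uword r0,
                              const Mat<eT>& dO, uword M, uword T,
                              bool fwd, Mat<eT>& dH, Mat<eT>& dWi,
                              Mat<eT>& dWh, Col<eT>& db) {
  dWi.zeros(160, 20); dWh.zeros(160, 40); db.zeros(160);
  Mat<eT> dh(40, M, fill::zeros), dc(40, M, fill::zeros), dG(160, M);
  Mat<eT> Ht(20, M), Hprev(40, M);
  for (uword step = 0; step < T; ++step) {
    const uword t = fwd ? T - 1 - step : step;   // reverse of forward order
    const bool first_step = fwd ? (t == 0) : (t == T - 1);
    for (uword m = 0; m < M; ++m) {
      const uword n = m * T + t;
      const eT* gc = G.colptr(n);
      const eT* cc = C.colptr(n);
      eT* dgc = dG.colptr(m);
      eT* dhc = dh.colptr(m);
      eT* dcc = dc.colptr(m);
      const uword nprev = fwd ? n - 1 : n + 1;   // previous processed step
      for (int r = 0; r < 40; ++r) {
        const double i_ = gc[r], f_ = gc[40 + r], z_ = gc[80 + r],
                     o_ = gc[120 + r];
        const double tc = std::tanh((double)cc[r]);
        const double dht = (double)dhc[r] + (double)dO(r0 + r, n);
        const double do_ = dht * tc * o_ * (1.0 - o_);
        double dct = (double)dcc[r] + dht * o_ * (1.0 - tc * tc);
        const double cprev = first_step ? 0.0 : (double)C(r, nprev);
        const double di = dct * z_ * i_ * (1.0 - i_);
        const double df = dct * cprev * f_ * (1.0 - f_);
        const double dz = dct * i_ * (1.0 - z_ * z_);
        dgc[r] = (eT)di; dgc[40 + r] = (eT)df;
        dgc[80 + r] = (eT)dz; dgc[120 + r] = (eT)do_;
        dcc[r] = (eT)(dct * f_);
      }
      std::memcpy(Ht.colptr(m), H.colptr(n), 20 * sizeof(eT));
      if (!first_step)
        for (int r = 0; r < 40; ++r) Hprev(r, m) = O(r0 + r, nprev);
      else
        std::memset(Hprev.colptr(m), 0, 40 * sizeof(eT));
    }
    dWi += dG * Ht.t();
    dWh += dG * Hprev.t();
    db += sum(dG, 1);
    Mat<eT> dx = Wi.t() * dG;
    for (uword m = 0; m < M; ++m) {
      eT* d = dH.colptr(m * T + t);
      const eT* s = dx.colptr(m);
      for (int r = 0; r < 20; ++r) d[r] += s[r];
    }
    dh = Wh.t() * dG;
  }
}

template <typename eT>
static List forward_impl(const List& params, const Rcpp::NumericVector& xarr,
                         bool training, bool ablate,
                         const std::string& precision) {
  Rcpp::IntegerVector dims = xarr.attr("dim");
  const uword M = dims[0], T = dims[1], S = dims[2];
  const uword N = M * T, L = S / 2, K = L * N;

  g_arena.reset();               // invalidates any earlier forward cache

  Cache<eT>* cp = new Cache<eT>(M, T, S);
  Cache<eT>& c = *cp;
  c.ablate = ablate;
  c.par = parse_params<eT>(params, ablate);
  Params<eT>& p = c.par;

  // rearrange (M,T,S) array into S x N, n = m*T + t
  {
    const double* xp = xarr.begin();
    for (uword s = 0; s < S; ++s)
      for (uword t = 0; t < T; ++t)
        for (uword m = 0; m < M; ++m)
          c.X0(s, m * T + t) = (eT)xp[m + M * (t + T * s)];
  }

  // ---- layer 1 (fused): conv(20,k7,p3) + LeakyReLU + maxpool(2); W1 is
  // 20 x 7 column-major, i.e. tap-major: column k = tap k of all kernels
  double bsum[20] = {0}, bsq[20] = {0};
  conv1_forward(c.X0, S, L, p.W1.memptr(), p.b1.memptr(), p.slope, c.P1pre,
                c.pidx, bsum, bsq);
  c.bn1 = training ? bn_affine_train(bsum, bsq, K, p.g1, p.be1)
                   : bn_affine_infer(p.rm1, p.rv1, p.g1, p.be1);

  // ---- batch-norm 1: O1 = a1 * P1pre + c1 ----
  affine_pass(c.P1pre, c.O1, c.bn1.a.memptr(), c.bn1.c.memptr());

  // ---- layer 2: O2 = O1 + bn2(LeakyReLU(conv(O1))) ----
  Mat<eT> A2 = arena_mat<eT>(20, K);
  conv3_forward(p.W2, c.O1, L, A2);
  std::fill(bsum, bsum + 20, 0.0); std::fill(bsq, bsq + 20, 0.0);
  bias_leaky_stats(A2, p.b2.memptr(), p.slope, bsum, bsq);
  c.bn2 = training ? bn_affine_train(bsum, bsq, K, p.g2, p.be2)
                   : bn_affine_infer(p.rm2, p.rv2, p.g2, p.be2);
  bn_res_pass(A2, c.O1, c.O2, c.bn2.a.memptr(), c.bn2.c.memptr());

  // ---- layer 3: O3 = O2 + bn3(LeakyReLU(conv(O2))); only the bn-path
  // output D3 is kept, and global average pooling over O3 = O2 + D3 is
  // fused into the same pass ----
  conv3_forward(p.W3, c.O2, L, c.D3);
  std::fill(bsum, bsum + 20, 0.0); std::fill(bsq, bsq + 20, 0.0);
  bias_leaky_stats(c.D3, p.b3.memptr(), p.slope, bsum, bsq);
  c.bn3 = training ? bn_affine_train(bsum, bsq, K, p.g3, p.be3)
                   : bn_affine_infer(p.rm3, p.rv3, p.g3, p.be3);
  c.H.set_size(20, N);
  bn_gap_pass(c.D3, c.O2, c.H, c.bn3.a.memptr(), c.bn3.c.memptr(), N, L);

  // ---- tracker ----
  if (!ablate) {
    c.O.set_size(80, N);
    lstm_dir(p.Wif, p.Whf, p.bif, c.H, M, T, true, c.Gf, c.Cf, c.O, 0,
             training);
    lstm_dir(p.Wib, p.Whb, p.bib, c.H, M, T, false, c.Gb, c.Cb, c.O, 40,
             training);
  } else {
    c.O = c.H;
  }

  // ---- softmax head: row 0 baseline, row 1 seizure ----
  Mat<eT> Z = p.Wo * c.O;
  Z.each_col() += p.bo;
  c.Pr.set_size(2, N);
  for (uword n = 0; n < N; ++n) {
    const double z0 = Z(0, n), z1 = Z(1, n);
    const double mz = std::max(z0, z1);
    const double e0 = std::exp(z0 - mz), e1 = std::exp(z1 - mz);
    c.Pr(0, n) = (eT)(e0 / (e0 + e1));
    c.Pr(1, n) = (eT)(e1 / (e0 + e1));
  }

  Rcpp::NumericMatrix probs(M, T);
  for (uword m = 0; m < M; ++m)
    for (uword t = 0; t < T; ++t)
      probs(m, t) = (double)c.Pr(1, m * T + t);

  List out = List::create(Named("probs") = probs);
  if (training) {
    out["ptr"] = Rcpp::XPtr<Cache<eT>>(cp, true);
    out["precision"] = precision;
    out["batch_stats"] = List::create(
        Named("bn1_mean") = Rcpp::wrap(conv_to<vec>::from(c.bn1.mu)),
        Named("bn1_var") =
            Rcpp::wrap(conv_to<vec>::from(square(c.bn1.sg) - (eT)BN_EPS)),
        Named("bn2_mean") = Rcpp::wrap(conv_to<vec>::from(c.bn2.mu)),
        Named("bn2_var") =
            Rcpp::wrap(conv_to<vec>::from(square(c.bn2.sg) - (eT)BN_EPS)),
        Named("bn3_mean") = Rcpp::wrap(conv_to<vec>::from(c.bn3.mu)),
        Named("bn3_var") =
            Rcpp::wrap(conv_to<vec>::from(square(c.bn3.sg) - (eT)BN_EPS)));
  } else {
    Rcpp::NumericMatrix hmat(20, N), omat(c.O.n_rows, N);
    for (uword j = 0; j < N; ++j) {
      for (uword r = 0; r < 20; ++r) hmat(r, j) = (double)c.H(r, j);
      for (uword r = 0; r < c.O.n_rows; ++r) omat(r, j) = (double)c.O(r, j);
    }
    out["h"] = hmat;
    out["o"] = omat;
    delete cp;
  }
  return out;
}

// clamp away zero-crossing gammas so the normalized activations can be
// reconstructed from the stored batch-norm outputs
template <typename eT>
static Col<eT> safe_inv_gamma(const Col<eT>& g) {
  Col<eT> inv(20);
  for (int r = 0; r < 20; ++r) {
    eT gg = g[r];
    if (std::abs((double)gg) < 1e-12) gg = gg < eT(0) ? eT(-1e-12) : eT(1e-12);
    inv[r] = eT(1) / gg;
  }
  return inv;
}

template <typename eT>
static List backward_impl(SEXP ptr, const Rcpp::NumericMatrix& dP) {
  Cache<eT>* cp = (Cache<eT>*)R_ExternalPtrAddr(ptr);
  if (!cp) Rcpp::stop("backward called twice on the same forward pass");
  Cache<eT>& c = *cp;
  if (c.gen != g_arena.gen)
    Rcpp::stop("forward cache was invalidated by a later forward pass");
  Params<eT>& p = c.par;
  const uword M = c.M, T = c.T, L = c.L, N = c.N, K = c.K;

  // head backward; only the seizure probability feeds the losses
  Mat<eT> dZ(2, N);
  for (uword m = 0; m < M; ++m) {
    for (uword t = 0; t < T; ++t) {
      const uword n = m * T + t;
      const double ps = c.Pr(1, n);
      const double g = (double)dP(m, t) * ps * (1.0 - ps);
      dZ(1, n) = (eT)g;
      dZ(0, n) = (eT)(-g);
    }
  }
  Mat<eT> dWo = dZ * c.O.t();
  Col<eT> dbo = sum(dZ, 1);
  Mat<eT> dO = p.Wo.t() * dZ;

  // tracker backward
  Mat<eT> dH;
  Mat<eT> dWif, dWhf, dWib, dWhb;
  Col<eT> dbif, dbib;
  if (!c.ablate) {
    dH.zeros(20, N);
    lstm_dir_backward(p.Wif, p.Whf, c.H, c.Gf, c.Cf, c.O, 0, dO, M, T, true,
                      dH, dWif, dWhf, dbif);
    lstm_dir_backward(p.Wib, p.Whb, c.H, c.Gb, c.Cb, c.O, 40, dO, M, T, false,
                      dH, dWib, dWhb, dbib);
  } else {
    dH = dO;
  }
  dH /= (eT)L;     // GAP backward: every position gets dH[:, n] / L

  // ---- layer 3 backward (dO3[:, j] = dH[:, n], already scaled by 1/L) ----
  Col<eT> ig3 = safe_inv_gamma(p.g3);
  Col<eT> gos3 = p.g3 / c.bn3.sg;
  Col<eT> sd3(20), sdx3(20);
  {
    Col<eT> gsum = conv_to<Col<eT>>::from(sum(dH, 1));
    double acc[20] = {0};
    bn_reduce_gap(dH, c.D3, p.be3.memptr(), ig3.memptr(), N, L, acc);
    for (int r = 0; r < 20; ++r) {
      sd3[r] = gsum[r] * (eT)L;
      sdx3[r] = (eT)acc[r];
    }
  }
  Mat<eT> dA3 = arena_mat<eT>(20, K);
  {
    Col<eT> m1 = sd3 / (eT)K, m2 = sdx3 / (eT)K;
    bn_apply_grad_gap(dH, c.D3, p.be3.memptr(), ig3.memptr(), gos3.memptr(),
                      m1.memptr(), m2.memptr(), c.bn3.sg.memptr(),
                      c.bn3.mu.memptr(), p.slope, N, L, dA3);
  }
  Mat<eT> dW3;
  Col<eT> db3;
  conv3_backward_weights(dA3, c.O2, L, dW3, db3);
  Mat<eT> dO2 = arena_mat<eT>(20, K);
  conv3_backward_data(p.W3, dA3, L, dO2, (const Mat<eT>*)nullptr, &dH);  // + residual/GAP
  // ---- layer 2 backward: xh2 = (O2 - O1 - be2)/g2 ----
  Col<eT> ig2 = safe_inv_gamma(p.g2);
  Col<eT> gos2 = p.g2 / c.bn2.sg;
  Col<eT> sd2(20), sdx2(20);
  {
    double asd[20] = {0}, asx[20] = {0};
    bn_reduce(dO2, c.O2, &c.O1, p.be2.memptr(), ig2.memptr(), asd, asx);
    for (int r = 0; r < 20; ++r) { sd2[r] = (eT)asd[r]; sdx2[r] = (eT)asx[r]; }
  }
  Mat<eT> dA2 = arena_mat<eT>(20, K);
  {
    Col<eT> m1 = sd2 / (eT)K, m2 = sdx2 / (eT)K;
    bn_apply_grad(dO2, c.O2, &c.O1, p.be2.memptr(), ig2.memptr(),
                  gos2.memptr(), m1.memptr(), m2.memptr(),
                  c.bn2.sg.memptr(), c.bn2.mu.memptr(), p.slope, dA2);
  }
  Mat<eT> dW2;
  Col<eT> db2;
  conv3_backward_weights(dA2, c.O1, L, dW2, db2);
  Mat<eT> dO1 = arena_mat<eT>(20, K);
  conv3_backward_data(p.W2, dA2, L, dO1, &dO2, (const Mat<eT>*)nullptr);  // + residual

  // ---- layer 1 backward (fused) ----
  Col<eT> ig1 = safe_inv_gamma(p.g1);
  Col<eT> gos1 = p.g1 / c.bn1.sg;
  Col<eT> sd1(20), sdx1(20);
  {
    double asd[20] = {0}, asx[20] = {0};
    bn_reduce(dO1, c.O1, (const Mat<eT>*)nullptr, p.be1.memptr(),
              ig1.memptr(), asd, asx);
    for (int r = 0; r < 20; ++r) { sd1[r] = (eT)asd[r]; sdx1[r] = (eT)asx[r]; }
  }
  Mat<eT> dW1(20, 7);
  Col<eT> db1(20);
  {
    Col<eT> m1 = sd1 / (eT)K, m2 = sdx1 / (eT)K;
    double w1acc[140] = {0}, b1acc[20] = {0};
    conv1_backward(dO1, c.O1, c.P1pre, c.pidx, c.X0, c.S, L, p.be1.memptr(),
                   ig1.memptr(), gos1.memptr(), m1.memptr(), m2.memptr(),
                   c.bn1.sg.memptr(), c.bn1.mu.memptr(), p.slope, w1acc,
                   b1acc);
    for (int r = 0; r < 20; ++r) {
      db1[r] = (eT)b1acc[r];
      for (int k = 0; k < 7; ++k) dW1(r, k) = (eT)w1acc[r + 20 * k];
    }
  }

  auto wrapM = [](const Mat<eT>& m) {
    return Rcpp::wrap(conv_to<mat>::from(m));
  };
  auto wrapC = [](const Col<eT>& v) {
    return Rcpp::wrap(conv_to<vec>::from(v));
  };
  List out = List::create(
      Named("conv1_w") = wrapM(dW1), Named("conv1_b") = wrapC(db1),
      Named("bn1_gamma") = wrapC(sdx1), Named("bn1_beta") = wrapC(sd1),
      Named("conv2_w") = wrapM(dW2), Named("conv2_b") = wrapC(db2),
      Named("bn2_gamma") = wrapC(sdx2), Named("bn2_beta") = wrapC(sd2),
      Named("conv3_w") = wrapM(dW3), Named("conv3_b") = wrapC(db3),
      Named("bn3_gamma") = wrapC(sdx3), Named("bn3_beta") = wrapC(sd3),
      Named("head_w") = wrapM(dWo), Named("head_b") = wrapC(dbo));
  if (!c.ablate) {
    out["lstm_f_wi"] = wrapM(dWif); out["lstm_f_wh"] = wrapM(dWhf);
    out["lstm_f_b"] = wrapC(dbif);
    out["lstm_b_wi"] = wrapM(dWib); out["lstm_b_wh"] = wrapM(dWhb);
    out["lstm_b_b"] = wrapC(dbib);
  }
  // free the cache now (it can be hundreds of MB); the registered
  // finalizer then sees a cleared pointer and is a no-op
  delete cp;
  R_ClearExternalPtr(ptr);
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".net_forward_cpp")]]
List net_forward_cpp(List params, Rcpp::NumericVector x, bool training,
                     bool ablate, std::string precision) {
  if (precision == "double")
    return forward_impl<double>(params, x, training, ablate, precision);
  return forward_impl<float>(params, x, training, ablate, precision);
}

//' @noRd
// [[Rcpp::export(name = ".net_backward_cpp")]]
List net_backward_cpp(SEXP ptr, Rcpp::NumericMatrix dP, std::string precision) {
  if (precision == "double") return backward_impl<double>(ptr, dP);
  return backward_impl<float>(ptr, dP);
}

// single-direction LSTM over one channel's embedding sequence (inference
// helper for the operation-level API; bidirectionality is composed in R)
//' @noRd
// [[Rcpp::export(name = ".lstm_seq_cpp")]]
Rcpp::NumericMatrix lstm_seq_cpp(Rcpp::NumericMatrix Wi, Rcpp::NumericMatrix Wh,
                                 Rcpp::NumericVector b, Rcpp::NumericMatrix H) {
  mat Wi_ = Rcpp::as<mat>(Wi), Wh_ = Rcpp::as<mat>(Wh), H_ = Rcpp::as<mat>(H);
  vec b_ = Rcpp::as<vec>(b);
  const uword T = H_.n_cols;
  mat G, C, O(40, T);
  lstm_dir<double>(Wi_, Wh_, b_, H_, 1, T, true, G, C, O, 0, false);
  return Rcpp::wrap(O);
}
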
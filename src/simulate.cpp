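#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// A haplotype genome as ancestry tracts, chromosomes concatenated.
// ends[i] is the right (exclusive) boundary of tract i in Morgans on its own
// chromosome's coordinate system; off has nChrom+1 entries delimiting the
// tract range of each chromosome. Tracts tile [0, L_c) with no gaps and
// adjacent tracts on a chromosome always differ in ancestry.
struct Hap {
    std::vector<double> ends;
    std::vector<int> anc;
    std::vector<int> off;
};

static inline void emit_tract(Hap &child, int base, double end, int a) {
    if ((int)child.ends.size() > base && child.anc.back() == a)
        child.ends.back() = end; // merge with previous same-ancestry tract
    else {
        child.ends.push_back(end);
        child.anc.push_back(a);
    }
}

// Copy the ancestry of parent hap P on chromosome c over [x0, x1) into child.
// cur is a forward-only cursor into P's tract list for this chromosome.
static void copy_range(const Hap &P, int c, double x0, double x1, int &cur,
                       Hap &child, int base) {
    int hi = P.off[c + 1];
    while (cur < hi - 1 && P.ends[cur] <= x0) ++cur;
    for (int i = cur; i < hi; ++i) {
        if (P.ends[i] >= x1) {
            emit_tract(child, base, x1, P.anc[i]);
            break;
        }
        emit_tract(child, base, P.ends[i], P.anc[i]);
    }
}

// One meiosis: recombine haplotypes A and B into a gamete. Crossover count
// per chromosome is Poisson(length in Morgans), breakpoints i.i.d. uniform
// (no interference); the starting haplotype is a fair coin flip.
static void meiosis(const Hap &A, const Hap &B, const std::vector<double> &len,
                    Hap &child) {
    int nChrom = (int)len.size();
    child.ends.clear();
    child.anc.clear();
    child.off.assign(nChrom + 1, 0);
    std::vector<double> bp;
    for (int c = 0; c < nChrom; ++c) {
        int base = (int)child.ends.size();
        double L = len[c];
        int k = (int)R::rpois(L);
        int src = (unif_rand() < 0.5) ? 0 : 1;
        if (k == 0) {
            const Hap &P = src ? B : A;
            for (int i = P.off[c]; i < P.off[c + 1]; ++i) {
                child.ends.push_back(P.ends[i]);
                child.anc.push_back(P.anc[i]);
            }
        } else {
            bp.resize(k);
            for (int j = 0; j < k; ++j) bp[j] = unif_rand() * L;
            std::sort(bp.begin(), bp.end());
            int curA = A.off[c], curB = B.off[c];
            double x0 = 0.0;
            for (int j = 0; j <= k; ++j) {
                double x1 = (j == k) ? L : bp[j];
                if (x1 > x0) {
                    copy_range(src ? B : A, c, x0, x1, src ? curB : curA,
                               child, base);
                    x0 = x1;
                }
                src ^= 1;
            }
        }
        child.off[c + 1] = (int)child.ends.size();
    }
}

static Hap founder_hap(int ancestry, const std::vector<double> &len) {
    Hap h;
    int n = (int)len.size();
    h.ends.assign(len.begin(), len.end());
    h.anc.assign(n, ancestry);
    h.off.resize(n + 1);
    for (int c = 0; c <= n; ++c) h.off[c] = c;
    return h;
}

static int draw_ancestry(const std::vector<double> &cum) {
    double u = unif_rand();
    for (int a = 0; a < (int)cum.size(); ++a)
        if (u < cum[a]) return a;
    return (int)cum.size() - 1;
}

static List pack_sample(const std::vector<const Hap *> &haps) {
    R_xlen_t total = 0;
    for (const Hap *h : haps) total += (R_xlen_t)h->ends.size();
    NumericVector ends(total);
    IntegerVector anc(total);
    int nChrom = haps.empty() ? 0 : (int)haps[0]->off.size() - 1;
    IntegerVector off((R_xlen_t)haps.size() * nChrom + 1);
    R_xlen_t pos = 0, oi = 0;
    off[oi++] = 0;
    for (const Hap *h : haps) {
        for (int c = 0; c < nChrom; ++c) {
            for (int i = h->off[c]; i < h->off[c + 1]; ++i) {
                ends[pos] = h->ends[i];
                anc[pos] = h->anc[i];
                ++pos;
            }
            off[oi++] = (int)pos;
        }
    }
    return List::create(_["ends"] = ends, _["anc"] = anc, _["off"] = off,
                        _["n_hap"] = (int)haps.size(),
                        _["n_chrom"] = nChrom);
}

// Forward Wright-Fisher simulation of a single admixture pulse.
// Generation 0 holds 2*Ne single-ancestry founder haplotypes drawn i.i.d.
// from `props`; each later generation is built by sampling, for every one of
// the Ne offspring, two parents uniformly (with replacement) and one gamete
// from each. In two-sex mode individuals 0..nF-1 of every generation are
// female and the two parents come one from each sex pool. After T
// generations n_sample diploids are drawn without replacement.
// [[Rcpp::export(name = ".wf_simulate")]]
List wf_simulate(NumericVector chrom_len, NumericVector props, int ne,
                 int gens, int n_sample, bool two_sex, int n_female) {
    RNGScope scope;
    int nChrom = chrom_len.size(), nAnc = props.size();
    std::vector<double> len(chrom_len.begin(), chrom_len.end());
    std::vector<double> cum(nAnc);
    double s = 0.0;
    for (int a = 0; a < nAnc; ++a) { s += props[a]; cum[a] = s; }
    cum[nAnc - 1] = 1.0;

    std::vector<Hap> pop(2 * (size_t)ne), next(2 * (size_t)ne);
    IntegerVector founderCount(nAnc);
    for (int i = 0; i < 2 * ne; ++i) {
        int a = draw_ancestry(cum);
        ++founderCount[a];
        pop[i] = founder_hap(a, len);
    }

    int nF = two_sex ? n_female : 0;
    for (int g = 0; g < gens; ++g) {
        for (int i = 0; i < ne; ++i) {
            int m, f;
            if (two_sex) {
                m = (int)(unif_rand() * nF);
                if (m >= nF) m = nF - 1;
                f = nF + (int)(unif_rand() * (ne - nF));
                if (f >= ne) f = ne - 1;
            } else {
                m = (int)(unif_rand() * ne);
                if (m >= ne) m = ne - 1;
                f = (int)(unif_rand() * ne);
                if (f >= ne) f = ne - 1;
            }
            meiosis(pop[2 * m], pop[2 * m + 1], len, next[2 * i]);
            meiosis(pop[2 * f], pop[2 * f + 1], len, next[2 * i + 1]);
        }
        std::swap(pop, next);
        Rcpp::checkUserInterrupt();
    }

    // partial Fisher-Yates draw of n_sample individuals without replacement
    std::vector<int> idx(ne);
    for (int i = 0; i < ne; ++i) idx[i] = i;
    IntegerVector chosen(n_sample);
    for (int i = 0; i < n_sample; ++i) {
        int j = i + (int)(unif_rand() * (ne - i));
        if (j >= ne) j = ne - 1;
        std::swap(idx[i], idx[j]);
        chosen[i] = idx[i];
    }

    std::vector<const Hap *> haps;
    haps.reserve(2 * (size_t)n_sample);
    for (int i = 0; i < n_sample; ++i) {
        haps.push_back(&pop[2 * chosen[i]]);
        haps.push_back(&pop[2 * chosen[i] + 1]);
    }
    List out = pack_sample(haps);
    out["founder_count"] = founderCount;
    out["chosen"] = chosen; // 0-based individual indices (sex = idx < nF)
    return out;
}

static Hap unpack_hap(NumericVector ends, IntegerVector anc,
                      IntegerVector off) {
    Hap h;
    h.ends.assign(ends.begin(), ends.end());
    h.anc.assign(anc.begin(), anc.end());
    h.off.assign(off.begin(), off.end());
    return h;
}

// Single meiosis on flat tract arrays (off has n_chrom+1 entries per hap).
// [[Rcpp::export(name = ".meiosis_one")]]
List meiosis_one(NumericVector endsA, IntegerVector ancA, IntegerVector offA,
                 NumericVector endsB, IntegerVector ancB, IntegerVector offB,
                 NumericVector chrom_len) {
    RNGScope scope;
    Hap A = unpack_hap(endsA, ancA, offA), B = unpack_hap(endsB, ancB, offB);
    std::vector<double> len(chrom_len.begin(), chrom_len.end());
    Hap child;
    meiosis(A, B, len, child);
    std::vector<const Hap *> one{&child};
    return pack_sample(one);
}

// Project tract genomes onto SNP positions. snp_gpos must be grouped by
// chromosome: snp_off[c]..snp_off[c+1]-1 are the SNPs of chromosome c,
// positions non-decreasing. Returns an n_hap x n_snp integer matrix of
// ancestry codes; a SNP at genetic position g takes the tract whose
// half-open interval [start, end) contains g (g == chromosome length falls
// into the last tract).
// [[Rcpp::export(name = ".project_tracts")]]
IntegerMatrix project_tracts(NumericVector ends, IntegerVector anc,
                             IntegerVector off, int n_hap, int n_chrom,
                             NumericVector snp_gpos, IntegerVector snp_off) {
    int n_snp = snp_gpos.size();
    IntegerMatrix out(n_hap, n_snp);
    for (int h = 0; h < n_hap; ++h) {
        for (int c = 0; c < n_chrom; ++c) {
            int lo = off[h * n_chrom + c], hi = off[h * n_chrom + c + 1];
            int t = lo;
            for (int s = snp_off[c]; s < snp_off[c + 1]; ++s) {
                double g = snp_gpos[s];
                while (t < hi - 1 && ends[t] <= g) ++t;
                out(h, s) = anc[t];
            }
            // rewind not needed: SNPs within a chromosome are sorted
        }
    }
    return out;
}
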
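// Forward-in-time Wright-Fisher simulator of TE invasions with transposon
// traps (piRNA-cluster-like silencing regions), neutral reference regions,
// uniform recombination, per-copy transposition and optional site-class
// selection. All randomness flows through R's RNG so that set.seed() in R
// makes every entry point deterministic.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
#include <unordered_map>

using namespace Rcpp;

namespace {

// A haplotype is a sorted, duplicate-free vector of global 0-based insertion
// positions (chrom * L + pos) with a parallel vector of 1-based effect-class
// indices.
struct Hap {
    std::vector<int> pos;
    std::vector<int> cls;
};

struct Ind {
    Hap h[2];
};

struct Arch {
    int nChrom;
    int L;                      // chromosome length in bp
    double xoverMean;           // expected crossovers per chromosome per meiosis
    std::vector<int> trapStart, trapEnd;  // global 0-based half-open, sorted
    std::vector<int> refStart, refEnd;
    double G() const { return (double)nChrom * (double)L; }
};

struct Sel {
    std::vector<double> x;        // selection coefficient per effect class
    std::vector<double> cumFrac;  // cumulative class fractions (sums to 1)
    bool trapsNeutral;
    bool allNeutral;
};

Arch parseArch(const List& a) {
    Arch r;
    r.nChrom = as<int>(a["nChrom"]);
    r.L = as<int>(a["chromLength"]);
    double recomb = as<double>(a["recombRate"]);    // cM/Mb
    r.xoverMean = recomb * (r.L / 1e6) / 100.0;     // Morgans per chromosome
    r.trapStart = as<std::vector<int> >(a["trapStart"]);
    r.trapEnd   = as<std::vector<int> >(a["trapEnd"]);
    r.refStart  = as<std::vector<int> >(a["refStart"]);
    r.refEnd    = as<std::vector<int> >(a["refEnd"]);
    return r;
}

Sel parseSel(const List& s) {
    Sel r;
    r.x = as<std::vector<double> >(s["x"]);
    std::vector<double> frac = as<std::vector<double> >(s["frac"]);
    r.cumFrac.resize(frac.size());
    double t = 0.0;
    for (size_t i = 0; i < frac.size(); ++i) { t += frac[i]; r.cumFrac[i] = t; }
    if (!r.cumFrac.empty()) r.cumFrac.back() = 1.0;
    r.trapsNeutral = as<bool>(s["trapsNeutral"]);
    r.allNeutral = true;
    for (size_t i = 0; i < r.x.size(); ++i)
        if (r.x[i] != 0.0) { r.allNeutral = false; break; }
    return r;
}

inline bool inIntervals(const std::vector<int>& s, const std::vector<int>& e, int p) {
    std::vector<int>::const_iterator it = std::upper_bound(s.begin(), s.end(), p);
    if (it == s.begin()) return false;
    size_t i = (it - s.begin()) - 1;
    return p < e[i];
}

inline bool hapHasIn(const Hap& h, const std::vector<int>& s, const std::vector<int>& e) {
    for (size_t i = 0; i < s.size(); ++i) {
        std::vector<int>::const_iterator it =
            std::lower_bound(h.pos.begin(), h.pos.end(), s[i]);
        if (it != h.pos.end() && *it < e[i]) return true;
    }
    return false;
}

inline int hapCountIn(const Hap& h, const std::vector<int>& s, const std::vector<int>& e) {
    int n = 0;
    for (size_t i = 0; i < s.size(); ++i) {
        std::vector<int>::const_iterator lo =
            std::lower_bound(h.pos.begin(), h.pos.end(), s[i]);
        std::vector<int>::const_iterator hi =
            std::lower_bound(h.pos.begin(), h.pos.end(), e[i]);
        n += (int)(hi - lo);
    }
    return n;
}

inline bool isSilencedC(const Ind& ind, const Arch& a) {
    return hapHasIn(ind.h[0], a.trapStart, a.trapEnd) ||
           hapHasIn(ind.h[1], a.trapStart, a.trapEnd);
}

// w = 1 - sum(x_i) over both haplotypes, trap insertions contributing 0 when
// trapsNeutral, clamped at 0.
double fitnessC(const Ind& ind, const Arch& a, const Sel& s) {
    if (s.allNeutral) return 1.0;
    double w = 1.0;
    for (int k = 0; k < 2; ++k) {
        const Hap& h = ind.h[k];
        for (size_t i = 0; i < h.pos.size(); ++i) {
            double x = s.x[h.cls[i] - 1];
            if (x == 0.0) continue;
            if (s.trapsNeutral && inIntervals(a.trapStart, a.trapEnd, h.pos[i]))
                continue;
            w -= x;
        }
    }
    return w > 0.0 ? w : 0.0;
}

inline void copyRange(const Hap& src, int lo, int hi, Hap& out) {
    if (lo >= hi) return;
    std::vector<int>::const_iterator a =
        std::lower_bound(src.pos.begin(), src.pos.end(), lo);
    std::vector<int>::const_iterator b =
        std::lower_bound(src.pos.begin(), src.pos.end(), hi);
    size_t ia = a - src.pos.begin(), ib = b - src.pos.begin();
    out.pos.insert(out.pos.end(), src.pos.begin() + ia, src.pos.begin() + ib);
    out.cls.insert(out.cls.end(), src.cls.begin() + ia, src.cls.begin() + ib);
}

// Crossover count ~ Poisson(Morgans per chromosome); breakpoint positions
// continuous uniform, floored to bp; a crossover at p splits [0,p) | [p,L);
// the starting haplotype is a fair coin per chromosome and chromosomes
// assort independently.
void makeGameteC(const Ind& par, const Arch& a, Hap& out) {
    out.pos.clear();
    out.cls.clear();
    for (int c = 0; c < a.nChrom; ++c) {
        double lo = (double)c * a.L, hi = lo + a.L;
        int cur = (unif_rand() < 0.5) ? 0 : 1;
        int k = (int)R::rpois(a.xoverMean);
        if (k == 0) {
            copyRange(par.h[cur], (int)lo, (int)hi, out);
            continue;
        }
        std::vector<int> bp((size_t)k);
        for (int j = 0; j < k; ++j)
            bp[j] = (int)(lo + std::floor(unif_rand() * a.L));
        std::sort(bp.begin(), bp.end());
        int segLo = (int)lo;
        for (int j = 0; j <= k; ++j) {
            int segHi = (j < k) ? bp[j] : (int)hi;
            copyRange(par.h[cur], segLo, segHi, out);
            segLo = segHi;
            cur ^= 1;
        }
    }
}

int drawClass(const Sel& s) {
    double r = unif_rand();
    for (size_t i = 0; i < s.cumFrac.size(); ++i)
        if (r < s.cumFrac[i]) return (int)i + 1;
    return (int)s.cumFrac.size();
}

// Insert a new copy at a uniformly random unoccupied position of haplotype h.
void insertUniform(Hap& h, const Arch& a, const Sel& s) {
    for (;;) {
        double d = std::floor(unif_rand() * a.G());
        if (d >= a.G()) continue;
        int p = (int)d;
        std::vector<int>::iterator it =
            std::lower_bound(h.pos.begin(), h.pos.end(), p);
        if (it != h.pos.end() && *it == p) continue;  // redraw on collision
        size_t idx = it - h.pos.begin();
        h.pos.insert(it, p);
        h.cls.insert(h.cls.begin() + idx, drawClass(s));
        return;
    }
}

struct ParentSampler {
    bool uniform;
    int N;
    std::vector<double> cum;
    double tot;
    int draw() const {
        if (uniform) {
            int i = (int)(unif_rand() * N);
            return i >= N ? N - 1 : i;
        }
        double r = unif_rand() * tot;
        std::vector<double>::const_iterator it =
            std::upper_bound(cum.begin(), cum.end(), r);
        int i = (int)(it - cum.begin());
        return i >= N ? N - 1 : i;
    }
};

// One Wright-Fisher generation: two parents per offspring sampled with
// probability proportional to fitness (uniform under full neutrality), one
// gamete per parent, then per-copy transposition. Under parent conditioning
// (the default) only copies inherited from a non-silenced parent transpose
// (transposition in the parental germline); under zygote conditioning a
// newly formed individual transposes all its copies at rate u unless it
// carries a trap insertion itself. Returns false when the total fitness is
// zero (reproduction impossible).
bool nextGenC(const std::vector<Ind>& pop, std::vector<Ind>& next,
              const std::vector<double>& w, const std::vector<char>& sil,
              const Arch& a, const Sel& s, double u, bool zygoteCond) {
    int N = (int)pop.size();
    ParentSampler ps;
    ps.N = N;
    ps.uniform = s.allNeutral;
    if (!ps.uniform) {
        ps.cum.resize(N);
        double t = 0.0;
        for (int i = 0; i < N; ++i) { t += w[i]; ps.cum[i] = t; }
        ps.tot = t;
        if (t <= 0.0) return false;
    }
    next.resize(N);
    for (int i = 0; i < N; ++i) {
        int p1 = ps.draw(), p2 = ps.draw();
        Ind& off = next[i];
        makeGameteC(pop[p1], a, off.h[0]);
        makeGameteC(pop[p2], a, off.h[1]);
        int nActive;
        if (zygoteCond) {
            nActive = isSilencedC(off, a)
                ? 0
                : (int)(off.h[0].pos.size() + off.h[1].pos.size());
        } else {
            nActive = (sil[p1] ? 0 : (int)off.h[0].pos.size()) +
                      (sil[p2] ? 0 : (int)off.h[1].pos.size());
        }
        if (u > 0.0 && nActive > 0) {
            int k = (int)R::rbinom((double)nActive, u);
            for (int j = 0; j < k; ++j)
                insertUniform(off.h[unif_rand() < 0.5 ? 0 : 1], a, s);
        }
    }
    return true;
}

std::string phaseC(const std::vector<Ind>& pop, const Arch& a) {
    int N = (int)pop.size();
    for (int i = 0; i < N; ++i)
        if (!isSilencedC(pop[i], a)) return "rapid";
    // all silenced: is any trap insertion fixed (present on all 2N haplotypes)?
    std::unordered_map<int, int> cnt;
    for (int i = 0; i < N; ++i) {
        for (int k = 0; k < 2; ++k) {
            const Hap& h = pop[i].h[k];
            for (size_t t = 0; t < a.trapStart.size(); ++t) {
                std::vector<int>::const_iterator lo =
                    std::lower_bound(h.pos.begin(), h.pos.end(), a.trapStart[t]);
                std::vector<int>::const_iterator hi =
                    std::lower_bound(h.pos.begin(), h.pos.end(), a.trapEnd[t]);
                for (std::vector<int>::const_iterator it = lo; it != hi; ++it)
                    cnt[*it]++;
            }
        }
    }
    for (std::unordered_map<int, int>::const_iterator it = cnt.begin();
         it != cnt.end(); ++it)
        if (it->second == 2 * N) return "inactive";
    return "shotgun";
}

void seedPopC(std::vector<Ind>& pop, int N, int nSeed, const Arch& a, const Sel& s) {
    pop.assign(N, Ind());
    for (int j = 0; j < nSeed; ++j) {
        int i = (int)(unif_rand() * N);
        if (i >= N) i = N - 1;
        Hap& h = pop[i].h[unif_rand() < 0.5 ? 0 : 1];
        insertUniform(h, a, s);
    }
}

// --- R <-> C++ conversion for the granular entry points ------------------

Hap hapFromList(const List& l) {
    Hap h;
    h.pos = as<std::vector<int> >(l["pos"]);
    h.cls = as<std::vector<int> >(l["cls"]);
    return h;
}

List hapToList(const Hap& h) {
    return List::create(Named("pos") = wrap(h.pos), Named("cls") = wrap(h.cls));
}

Ind indFromList(const List& l) {
    Ind d;
    d.h[0] = hapFromList(as<List>(l["h1"]));
    d.h[1] = hapFromList(as<List>(l["h2"]));
    return d;
}

List indToList(const Ind& d) {
    return List::create(Named("h1") = hapToList(d.h[0]),
                        Named("h2") = hapToList(d.h[1]));
}

std::vector<Ind> popFromList(const List& l) {
    std::vector<Ind> pop(l.size());
    for (R_xlen_t i = 0; i < l.size(); ++i) pop[(size_t)i] = indFromList(as<List>(l[i]));
    return pop;
}

List popToList(const std::vector<Ind>& pop) {
    List out(pop.size());
    for (size_t i = 0; i < pop.size(); ++i) out[i] = indToList(pop[i]);
    return out;
}

void countsOf(const std::vector<Ind>& pop, const Arch& a,
              IntegerVector& trap, IntegerVector& ref, IntegerVector& gen) {
    int N = (int)pop.size();
    for (int i = 0; i < N; ++i) {
        const Ind& d = pop[i];
        trap[i] = hapCountIn(d.h[0], a.trapStart, a.trapEnd) +
                  hapCountIn(d.h[1], a.trapStart, a.trapEnd);
        ref[i] = hapCountIn(d.h[0], a.refStart, a.refEnd) +
                 hapCountIn(d.h[1], a.refStart, a.refEnd);
        gen[i] = (int)(d.h[0].pos.size() + d.h[1].pos.size());
    }
}

} // namespace

// [[Rcpp::export]]
List seed_population_cpp(List archList, List selList, int N, int nSeed) {
    Arch a = parseArch(archList);
    Sel s = parseSel(selList);
    std::vector<Ind> pop;
    seedPopC(pop, N, nSeed, a, s);
    return popToList(pop);
}

// [[Rcpp::export]]
double fitness_cpp(List indList, List archList, List selList) {
    Arch a = parseArch(archList);
    Sel s = parseSel(selList);
    Ind d = indFromList(indList);
    return fitnessC(d, a, s);
}

// [[Rcpp::export]]
bool silenced_cpp(List indList, List archList) {
    Arch a = parseArch(archList);
    Ind d = indFromList(indList);
    return isSilencedC(d, a);
}

// [[Rcpp::export]]
List gamete_cpp(List indList, List archList) {
    Arch a = parseArch(archList);
    Ind d = indFromList(indList);
    Hap g;
    makeGameteC(d, a, g);
    return hapToList(g);
}

// [[Rcpp::export]]
List next_generation_cpp(List popList, List archList, List selList, double u,
                         bool zygoteConditioning = false) {
    Arch a = parseArch(archList);
    Sel s = parseSel(selList);
    std::vector<Ind> pop = popFromList(popList);
    int N = (int)pop.size();
    std::vector<double> w(N);
    std::vector<char> sil(N);
    for (int i = 0; i < N; ++i) {
        w[i] = fitnessC(pop[i], a, s);
        sil[i] = isSilencedC(pop[i], a) ? 1 : 0;
    }
    std::vector<Ind> nxt;
    if (!nextGenC(pop, nxt, w, sil, a, s, u, zygoteConditioning))
        stop("all individuals have fitness zero: population is extinct");
    return popToList(nxt);
}

// [[Rcpp::export]]
std::string classify_phase_cpp(List popList, List archList) {
    Arch a = parseArch(archList);
    std::vector<Ind> pop = popFromList(popList);
    return phaseC(pop, a);
}

// [[Rcpp::export]]
List region_counts_cpp(List popList, List archList) {
    Arch a = parseArch(archList);
    std::vector<Ind> pop = popFromList(popList);
    int N = (int)pop.size();
    IntegerVector trap(N), ref(N), gen(N);
    countsOf(pop, a, trap, ref, gen);
    return List::create(Named("trap") = trap, Named("reference") = ref,
                        Named("genome") = gen);
}

// [[Rcpp::export]]
List run_replicate_cpp(List archList, List selList, int N, double u, int nSeed,
                       int sampleGen, double extinctionFitness,
                       bool recordTrajectory = true, bool keepPopulation = false,
                       bool zygoteConditioning = false) {
    Arch a = parseArch(archList);
    Sel s = parseSel(selList);
    std::vector<Ind> pop, nxt;
    seedPopC(pop, N, nSeed, a, s);

    std::vector<double> trajGen, trajCopies, trajSil, trajTrap;
    std::vector<double> w((size_t)N);
    std::vector<char> sil((size_t)N);
    bool extinct = false;
    int firstAllSil = NA_INTEGER;
    double meanTrapAtSil = NA_REAL;
    std::string phase;
    IntegerVector cTrap(N), cRef(N), cGen(N);
    int gen = 0;

    for (gen = 0;; ++gen) {
        double sumW = 0.0, totIns = 0.0, totTrap = 0.0;
        int nSil = 0;
        for (int i = 0; i < N; ++i) {
            w[i] = fitnessC(pop[i], a, s);
            sumW += w[i];
            sil[i] = isSilencedC(pop[i], a) ? 1 : 0;
            nSil += sil[i];
            totIns += (double)(pop[i].h[0].pos.size() + pop[i].h[1].pos.size());
            totTrap += hapCountIn(pop[i].h[0], a.trapStart, a.trapEnd) +
                       hapCountIn(pop[i].h[1], a.trapStart, a.trapEnd);
        }
        if (recordTrajectory) {
            trajGen.push_back((double)gen);
            trajCopies.push_back(totIns / N);
            trajSil.push_back((double)nSil / N);
            trajTrap.push_back(totTrap / N);
        }
        if (firstAllSil == NA_INTEGER && nSil == N) {
            firstAllSil = gen;
            meanTrapAtSil = totTrap / N;
        }
        bool atSample = (gen >= sampleGen);
        // extinction is evaluated before reproduction each generation
        bool isExt = (sumW / N < extinctionFitness);
        if (atSample || isExt) {
            countsOf(pop, a, cTrap, cRef, cGen);
            extinct = isExt && !atSample;
            phase = extinct ? "extinct" : phaseC(pop, a);
            break;
        }
        if (!nextGenC(pop, nxt, w, sil, a, s, u, zygoteConditioning)) {
            countsOf(pop, a, cTrap, cRef, cGen);
            extinct = true;
            phase = "extinct";
            break;
        }
        pop.swap(nxt);
        if ((gen & 63) == 0) Rcpp::checkUserInterrupt();
    }

    List out = List::create(
        Named("trap") = cTrap,
        Named("reference") = cRef,
        Named("genome") = cGen,
        Named("phase") = phase,
        Named("extinct") = extinct,
        Named("generation") = gen,
        Named("firstAllSilenced") = firstAllSil,
        Named("meanTrapAtSilencing") = meanTrapAtSil,
        Named("trajectory") = DataFrame::create(
            Named("generation") = wrap(trajGen),
            Named("mean_diploid_copies") = wrap(trajCopies),
            Named("fraction_silenced") = wrap(trajSil),
            Named("mean_trap_diploid") = wrap(trajTrap)));
    if (keepPopulation) out["population"] = popToList(pop);
    return out;
}
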
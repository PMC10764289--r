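#ifndef FCCSFRET_RNG_H
#define FCCSFRET_RNG_H

#include <cstdint>
#include <cmath>
#include <cstdlib>

// Self-contained RNG stack (xoshiro256++ uniforms, Marsaglia-Tsang ziggurat
// normals, exact Poisson) so simulated traces are bit-reproducible from an
// integer seed and independent of R's RNG state.

class Rng {
public:
    explicit Rng(uint64_t seed) {
        // splitmix64 expansion of the seed into the xoshiro state
        uint64_t x = seed;
        for (int i = 0; i < 4; ++i) s_[i] = splitmix(x);
        zig_init();
    }

    uint64_t next() {
        const uint64_t result = rotl(s_[0] + s_[3], 23) + s_[0];
        const uint64_t t = s_[1] << 17;
        s_[2] ^= s_[0];
        s_[3] ^= s_[1];
        s_[1] ^= s_[2];
        s_[0] ^= s_[3];
        s_[2] ^= t;
        s_[3] = rotl(s_[3], 45);
        return result;
    }

    // uniform on [0, 1)
    double unif() {
        return (next() >> 11) * 1.1102230246251565e-16; // 2^-53
    }

    // uniform on (0, 1): avoids log(0) downstream
    double unif_pos() {
        double u;
        do { u = unif(); } while (u <= 0.0);
        return u;
    }

    // standard normal via 128-layer ziggurat
    double norm() {
        for (;;) {
            int32_t hz = static_cast<int32_t>(next() >> 32);
            uint32_t iz = static_cast<uint32_t>(hz) & 127u;
            uint32_t ahz = hz >= 0 ? static_cast<uint32_t>(hz)
                                   : static_cast<uint32_t>(-(int64_t)hz);
            if (ahz < kn_[iz]) return hz * wn_[iz];
            double x = nfix(hz, iz);
            if (std::isfinite(x)) return x;
        }
    }

    // exact Poisson (Knuth product method, chunked so it stays exact for
    // large means; means here are per-bin photon counts, rarely above ~50)
    int poisson(double lambda) {
        int n = 0;
        while (lambda > 30.0) {
            n += poisson_small(30.0);
            lambda -= 30.0;
        }
        return n + poisson_small(lambda);
    }

private:
    uint64_t s_[4];
    double wn_[128], fn_[128];
    uint32_t kn_[128];

    static uint64_t rotl(uint64_t x, int k) {
        return (x << k) | (x >> (64 - k));
    }

    static uint64_t splitmix(uint64_t &x) {
        x += 0x9E3779B97F4A7C15ULL;
        uint64_t z = x;
        z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
        z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
        return z ^ (z >> 31);
    }

    void zig_init() {
        const double m1 = 2147483648.0;
        double dn = 3.442619855899, tn = dn;
        const double vn = 9.91256303526217e-3;
        double q = vn / std::exp(-0.5 * dn * dn);
        kn_[0] = static_cast<uint32_t>((dn / q) * m1);
        kn_[1] = 0;
        wn_[0] = q / m1;
        wn_[127] = dn / m1;
        fn_[0] = 1.0;
        fn_[127] = std::exp(-0.5 * dn * dn);
        for (int i = 126; i >= 1; --i) {
            dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
            kn_[i + 1] = static_cast<uint32_t>((dn / tn) * m1);
            tn = dn;
            fn_[i] = std::exp(-0.5 * dn * dn);
            wn_[i] = dn / m1;
        }
    }

    // tail / wedge handling; returns NaN to request a fresh attempt
    double nfix(int32_t hz, uint32_t iz) {
        const double r = 3.442619855899;
        double x = hz * wn_[iz];
        if (iz == 0) {
            double y;
            do {
                x = -std::log(unif_pos()) / r;
                y = -std::log(unif_pos());
            } while (y + y < x * x);
            return hz > 0 ? r + x : -(r + x);
        }
        if (fn_[iz] + unif() * (fn_[iz - 1] - fn_[iz]) <
            std::exp(-0.5 * x * x)) {
            return x;
        }
        return std::nan("");
    }

    int poisson_small(double lambda) {
        if (lambda <= 0.0) return 0;
        const double l = std::exp(-lambda);
        int k = 0;
        double p = 1.0;
        do {
            ++k;
            p *= unif();
        } while (p > l);
        return k - 1;
    }
};

#endif
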
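{
  "nodes": [
    {
      "id": "M1",
      "props": {
        "znum": 65,
        "eneg": 1.36146194301546,
        "radius": 1.48386121476069
      }
    },
    {
      "id": "a1",
      "props": {
        "znum": 9,
        "eneg": 3.22305403235368,
        "radius": 0.670781895238906
      }
    },
    {
      "id": "a2",
      "props": {
        "znum": 13,
        "eneg": 3.30923496955074,
        "radius": 0.513953544502147
      }
    },
    {
      "id": "a3",
      "props": {
        "znum": 9,
        "eneg": 2.62242695675232,
        "radius": 0.531059798365459
      }
    },
    {
      "id": "a4",
      "props": {
        "znum": 18,
        "eneg": 3.2390564664267,
        "radius": 0.673874631896615
      }
    },
    {
      "id": "a5",
      "props": {
        "znum": 17,
        "eneg": 2.4874975102488,
        "radius": 0.591730846790597
      }
    },
    {
      "id": "a6",
      "props": {
        "znum": 18,
        "eneg": 3.16746221669018,
        "radius": 0.534342423733324
      }
    },
    {
      "id": "a7",
      "props": {
        "znum": 6,
        "eneg": 2.58619608390145,
        "radius": 0.753074264503084
      }
    },
    {
      "id": "a8",
      "props": {
        "znum": 13,
        "eneg": 3.42759189731441,
        "radius": 0.934688249789178
      }
    },
    {
      "id": "a9",
      "props": {
        "znum": 11,
        "eneg": 2.37516284496523,
        "radius": 0.885568209504709
      }
    },
    {
      "id": "a10",
      "props": {
        "znum": 18,
        "eneg": 1.94862436694093,
        "radius": 0.780837931809947
      }
    },
    {
      "id": "a11",
      "props": {
        "znum": 10,
        "eneg": 3.26932034287602,
        "radius": 0.861361058382317
      }
    },
    {
      "id": "a12",
      "props": {
        "znum": 14,
        "eneg": 3.41725719720125,
        "radius": 0.728109866031446
      }
    },
    {
      "id": "a13",
      "props": {
        "znum": 8,
        "eneg": 3.53969351593405,
        "radius": 0.737263877294026
      }
    },
    {
      "id": "a14",
      "props": {
        "znum": 7,
        "eneg": 2.83152398946695,
        "radius": 0.635944518912584
      }
    },
    {
      "id": "a15",
      "props": {
        "znum": 7,
        "eneg": 3.09614309370518,
        "radius": 0.697168411174789
      }
    },
    {
      "id": "a16",
      "props": {
        "znum": 10,
        "eneg": 3.1933055235073,
        "radius": 0.600910591683351
      }
    },
    {
      "id": "a17",
      "props": {
        "znum": 16,
        "eneg": 2.92996944095939,
        "radius": 0.820834072469734
      }
    },
    {
      "id": "a18",
      "props": {
        "znum": 11,
        "eneg": 3.10138081465848,
        "radius": 0.988519628439099
      }
    }
  ],
  "edges": [
    {
      "u": "M1",
      "v": "a1",
      "props": {
        "blen": 1.62079686345533,
        "border": 2.33472827766091
      }
    },
    {
      "u": "a1",
      "v": "a2",
      "props": {
        "blen": 1.61316559179686,
        "border": 1.97271199375391
      }
    },
    {
      "u": "a1",
      "v": "a3",
      "props": {
        "blen": 1.87306412556209,
        "border": 1.89608739260584
      }
    },
    {
      "u": "M1",
      "v": "a4",
      "props": {
        "blen": 2.30571467867121,
        "border": 1.451873796992
      }
    },
    {
      "u": "a4",
      "v": "a5",
      "props": {
        "blen": 2.24388961661607,
        "border": 2.57782041169703
      }
    },
    {
      "u": "a4",
      "v": "a6",
      "props": {
        "blen": 2.22995678549632,
        "border": 1.046728226915
      }
    },
    {
      "u": "a5",
      "v": "a7",
      "props": {
        "blen": 1.3390477267094,
        "border": 1.55129900481552
      }
    },
    {
      "u": "M1",
      "v": "a8",
      "props": {
        "blen": 2.03803531592712,
        "border": 1.766915705055
      }
    },
    {
      "u": "a8",
      "v": "a9",
      "props": {
        "blen": 1.54271883871406,
        "border": 1.7926581652835
      }
    },
    {
      "u": "M1",
      "v": "a10",
      "props": {
        "blen": 1.11053243428469,
        "border": 1.52889700625092
      }
    },
    {
      "u": "a10",
      "v": "a11",
      "props": {
        "blen": 1.13276977008209,
        "border": 2.14379412867129
      }
    },
    {
      "u": "a11",
      "v": "a12",
      "props": {
        "blen": 2.06699982355349,
        "border": 1.42519259210676
      }
    },
    {
      "u": "a12",
      "v": "a13",
      "props": {
        "blen": 1.48705163602717,
        "border": 2.8946497997269
      }
    },
    {
      "u": "a11",
      "v": "a14",
      "props": {
        "blen": 1.58347339252941,
        "border": 0.702508179657161
      }
    },
    {
      "u": "a12",
      "v": "a15",
      "props": {
        "blen": 1.48162272293121,
        "border": 2.43692975118756
      }
    },
    {
      "u": "M1",
      "v": "a16",
      "props": {
        "blen": 1.01177529180422,
        "border": 1.08904810231179
      }
    },
    {
      "u": "a16",
      "v": "a17",
      "props": {
        "blen": 2.27620498700999,
        "border": 2.24341095518321
      }
    },
    {
      "u": "a17",
      "v": "a18",
      "props": {
        "blen": 1.25508758602664,
        "border": 1.55080260839313
      }
    }
  ],
  "metal": "M1"
}
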
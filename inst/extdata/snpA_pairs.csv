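subject_id,locus_id,gold_call,observed_call
val_001,SNP_A,AA,AA
val_002,SNP_A,AA,AA
val_003,SNP_A,AA,AA
val_004,SNP_A,AA,AA
val_005,SNP_A,AA,AA
val_006,SNP_A,AA,AA
val_007,SNP_A,AA,AA
val_008,SNP_A,AA,AA
val_009,SNP_A,AA,AA
val_010,SNP_A,AA,AA
val_011,SNP_A,AA,AA
val_012,SNP_A,AA,AA
val_013,SNP_A,AA,AA
val_014,SNP_A,AA,AA
val_015,SNP_A,AA,AA
val_016,SNP_A,AA,AA
val_017,SNP_A,AA,AA
val_018,SNP_A,AA,AA
val_019,SNP_A,AA,AA
val_020,SNP_A,AA,AA
val_021,SNP_A,AA,AA
val_022,SNP_A,AA,AA
val_023,SNP_A,AA,AA
val_024,SNP_A,AA,AA
val_025,SNP_A,AA,AA
val_026,SNP_A,AA,AA
val_027,SNP_A,AA,AA
val_028,SNP_A,AA,AA
val_029,SNP_A,AA,AA
val_030,SNP_A,AA,AA
val_031,SNP_A,AA,AA
val_032,SNP_A,AA,AA
val_033,SNP_A,AA,AA
val_034,SNP_A,AA,AA
val_035,SNP_A,AA,AA
val_036,SNP_A,AA,AA
val_037,SNP_A,AA,AA
val_038,SNP_A,AA,AA
val_039,SNP_A,AA,AA
val_040,SNP_A,AA,AA
val_041,SNP_A,AA,AA
val_042,SNP_A,AA,AA
val_043,SNP_A,AA,AA
val_044,SNP_A,AA,AA
val_045,SNP_A,AA,AA
val_046,SNP_A,AA,AA
val_047,SNP_A,AA,AA
val_048,SNP_A,AA,AA
val_049,SNP_A,AA,AA
val_050,SNP_A,AA,AA
val_051,SNP_A,AA,AA
val_052,SNP_A,AA,AA
val_053,SNP_A,AA,AA
val_054,SNP_A,AA,AA
val_055,SNP_A,AA,AA
val_056,SNP_A,AA,AA
val_057,SNP_A,AA,AA
val_058,SNP_A,AA,AA
val_059,SNP_A,AA,AA
val_060,SNP_A,AA,AA
val_061,SNP_A,AA,AA
val_062,SNP_A,AA,AA
val_063,SNP_A,AA,AA
val_064,SNP_A,AA,AA
val_065,SNP_A,AA,AA
val_066,SNP_A,AA,AA
val_067,SNP_A,AA,AA
val_068,SNP_A,AA,AA
val_069,SNP_A,AA,AA
val_070,SNP_A,AA,AA
val_071,SNP_A,AA,AA
val_072,SNP_A,AA,AA
val_073,SNP_A,AA,AA
val_074,SNP_A,AA,AA
val_075,SNP_A,AA,AA
val_076,SNP_A,AA,AA
val_077,SNP_A,AA,AA
val_078,SNP_A,AA,AA
val_079,SNP_A,AA,AA
val_080,SNP_A,AA,AA
val_081,SNP_A,AA,AA
val_082,SNP_A,AA,AA
val_083,SNP_A,AA,AA
val_084,SNP_A,AA,AA
val_085,SNP_A,AA,AA
val_086,SNP_A,AA,AA
val_087,SNP_A,AA,AA
val_088,SNP_A,AA,AA
val_089,SNP_A,AA,AA
val_090,SNP_A,AA,AA
val_091,SNP_A,AA,AA
val_092,SNP_A,AA,AA
val_093,SNP_A,AA,AA
val_094,SNP_A,AA,AA
val_095,SNP_A,AA,AA
val_096,SNP_A,Aa,AA
val_097,SNP_A,AA,Aa
val_098,SNP_A,Aa,Aa
val_099,SNP_A,Aa,Aa
val_100,SNP_A,Aa,Aa
val_101,SNP_A,Aa,Aa
val_102,SNP_A,Aa,Aa
val_103,SNP_A,Aa,Aa
val_104,SNP_A,Aa,Aa
val_105,SNP_A,Aa,Aa
val_106,SNP_A,Aa,Aa
val_107,SNP_A,Aa,Aa
val_108,SNP_A,Aa,Aa
val_109,SNP_A,Aa,Aa
val_110,SNP_A,Aa,Aa
val_111,SNP_A,Aa,Aa
val_112,SNP_A,Aa,Aa
val_113,SNP_A,Aa,Aa
val_114,SNP_A,Aa,Aa
val_115,SNP_A,Aa,Aa
val_116,SNP_A,Aa,Aa
val_117,SNP_A,Aa,Aa
val_118,SNP_A,Aa,Aa
val_119,SNP_A,Aa,Aa
val_120,SNP_A,Aa,Aa
val_121,SNP_A,Aa,Aa
val_122,SNP_A,Aa,Aa
val_123,SNP_A,Aa,Aa
val_124,SNP_A,Aa,Aa
val_125,SNP_A,Aa,Aa
val_126,SNP_A,Aa,Aa
val_127,SNP_A,Aa,Aa
val_128,SNP_A,Aa,Aa
val_129,SNP_A,Aa,Aa
val_130,SNP_A,Aa,Aa
val_131,SNP_A,Aa,Aa
val_132,SNP_A,Aa,Aa
val_133,SNP_A,Aa,Aa
val_134,SNP_A,Aa,Aa
val_135,SNP_A,Aa,Aa
val_136,SNP_A,Aa,Aa
val_137,SNP_A,Aa,Aa
val_138,SNP_A,Aa,Aa
val_139,SNP_A,Aa,Aa
val_140,SNP_A,Aa,Aa
val_141,SNP_A,Aa,Aa
val_142,SNP_A,Aa,Aa
val_143,SNP_A,Aa,Aa
val_144,SNP_A,Aa,Aa
val_145,SNP_A,Aa,Aa
val_146,SNP_A,Aa,Aa
val_147,SNP_A,Aa,Aa
val_148,SNP_A,Aa,Aa
val_149,SNP_A,Aa,Aa
val_150,SNP_A,Aa,Aa
val_151,SNP_A,Aa,Aa
val_152,SNP_A,Aa,Aa
val_153,SNP_A,Aa,Aa
val_154,SNP_A,Aa,Aa
val_155,SNP_A,Aa,Aa
val_156,SNP_A,Aa,Aa
val_157,SNP_A,Aa,Aa
val_158,SNP_A,Aa,Aa
val_159,SNP_A,Aa,Aa
val_160,SNP_A,Aa,Aa
val_161,SNP_A,Aa,Aa
val_162,SNP_A,Aa,Aa
val_163,SNP_A,Aa,Aa
val_164,SNP_A,Aa,Aa
val_165,SNP_A,Aa,Aa
val_166,SNP_A,Aa,Aa
val_167,SNP_A,Aa,Aa
val_168,SNP_A,Aa,Aa
val_169,SNP_A,Aa,Aa
val_170,SNP_A,Aa,Aa
val_171,SNP_A,Aa,Aa
val_172,SNP_A,Aa,Aa
val_173,SNP_A,Aa,Aa
val_174,SNP_A,Aa,Aa
val_175,SNP_A,Aa,Aa
val_176,SNP_A,Aa,Aa
val_177,SNP_A,Aa,Aa
val_178,SNP_A,Aa,Aa
val_179,SNP_A,Aa,Aa
val_180,SNP_A,Aa,Aa
val_181,SNP_A,Aa,Aa
val_182,SNP_A,Aa,Aa
val_183,SNP_A,Aa,Aa
val_184,SNP_A,Aa,Aa
val_185,SNP_A,Aa,Aa
val_186,SNP_A,Aa,Aa
val_187,SNP_A,Aa,Aa
val_188,SNP_A,Aa,aa
val_189,SNP_A,Aa,aa
val_190,SNP_A,Aa,aa
val_191,SNP_A,aa,aa
val_192,SNP_A,aa,aa
val_193,SNP_A,aa,aa
val_194,SNP_A,aa,aa
val_195,SNP_A,aa,aa
val_196,SNP_A,aa,aa
val_197,SNP_A,aa,aa
val_198,SNP_A,aa,aa
val_199,SNP_A,aa,aa
val_200,SNP_A,aa,aa
val_201,SNP_A,aa,aa
val_202,SNP_A,aa,aa
val_203,SNP_A,aa,aa
val_204,SNP_A,aa,aa
val_205,SNP_A,aa,aa
val_206,SNP_A,aa,aa
val_207,SNP_A,aa,aa
val_208,SNP_A,aa,aa
val_209,SNP_A,aa,aa
val_210,SNP_A,aa,aa
val_211,SNP_A,aa,aa
val_212,SNP_A,aa,aa
val_213,SNP_A,aa,aa
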
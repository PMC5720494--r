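/* generated index map: species (0-based) */
#define S_INK4A 0
#define S_ARF 1
#define S_MYC 2
#define S_WEE1 3
#define S_MDM2 4
#define S_P53 5
#define S_E2F 6
#define S_INK4A_C 7
#define S_MYC_C 8
#define S_ARF_C 9
#define S_MDM2_C 10
#define S_E2F_C 11
#define S_WEE1_C 12
#define S_INK4A_N 13
#define S_MYC_N 14
#define S_P53_N 15
#define S_MDM2_N 16
#define S_WEE1_N 17
#define S_ARF_N 18
#define S_RB1_N 19
#define S_RBE2F 20
#define S_E2F_N 21
#define S_CDC 22
#define S_CDC_C 23
#define S_CDC_N 24
#define S_CDCI 25
#define S_RB1P_N 26
#define S_BMAL 27
#define S_PER 28
#define S_CRY 29
#define S_REV 30
#define S_ROR 31
#define S_BMAL_C 32
#define S_PER_C 33
#define S_CRY_C 34
#define S_REV_C 35
#define S_ROR_C 36
#define S_BMAL_N 37
#define S_PER_N 38
#define S_CRY_N 39
#define S_REV_N 40
#define S_ROR_N 41
#define S_PERCRY_C 42
#define S_PERCRY_N 43
#define S_CB 44
#define S_CBI 45

/* generated index map: parameters (0-based) */
#define P_VB_INK 0
#define P_V_INK 1
#define P_KA_INK_PC 2
#define P_HA_INK_PC 3
#define P_KM_INK 4
#define P_DM_INK 5
#define P_VB_ARF 6
#define P_V_ARF 7
#define P_KA_ARF_MYC 8
#define P_HA_ARF_MYC 9
#define P_KM_ARF 10
#define P_DM_ARF 11
#define P_VB_MYC 12
#define P_V_MYC 13
#define P_KI_MYC_CB 14
#define P_HI_MYC_CB 15
#define P_KM_MYC 16
#define P_DM_MYC 17
#define P_VB_WEE1 18
#define P_V_WEE1 19
#define P_KA_WEE1_CB 20
#define P_HA_WEE1_CB 21
#define P_KM_WEE1 22
#define P_DM_WEE1 23
#define P_VB_MDM2 24
#define P_V_MDM2 25
#define P_KA_MDM2_P53 26
#define P_HA_MDM2_P53 27
#define P_KM_MDM2 28
#define P_DM_MDM2 29
#define P_VB_P53 30
#define P_KM_P53 31
#define P_DM_P53 32
#define P_VB_E2F 33
#define P_V_E2F 34
#define P_KA_E2F_MYC 35
#define P_HA_E2F_MYC 36
#define P_V_E2F_AUTO 37
#define P_KA_E2F_AUTO 38
#define P_HA_E2F_AUTO 39
#define P_KM_E2F 40
#define P_DM_E2F 41
#define P_VB_CDC 42
#define P_V_CDC 43
#define P_KA_CDC_E2F 44
#define P_HA_CDC_E2F 45
#define P_KM_CDC 46
#define P_DM_CDC 47
#define P_KT_INK4A 48
#define P_KI_INK4A 49
#define P_DC_INK4A 50
#define P_KT_MYC 51
#define P_KI_MYC 52
#define P_DC_MYC 53
#define P_KT_ARF 54
#define P_KI_ARF 55
#define P_DC_ARF 56
#define P_KT_MDM2 57
#define P_KI_MDM2 58
#define P_DC_MDM2 59
#define P_KT_E2F 60
#define P_KI_E2F 61
#define P_DC_E2F 62
#define P_KT_WEE1 63
#define P_KI_WEE1 64
#define P_DC_WEE1 65
#define P_KT_CDC 66
#define P_KI_CDC 67
#define P_DC_CDC 68
#define P_DN_INK4A 69
#define P_KF_ICK 70
#define P_KD_ICK 71
#define P_DN_MYC 72
#define P_KT_P53 73
#define P_D_P53 74
#define P_V_DP53_MDM2 75
#define P_KD_P53_MDM2 76
#define P_HD_P53_MDM2 77
#define P_DN_MDM2 78
#define P_V_DMDM2_ARF 79
#define P_KD_MDM2_ARF 80
#define P_HD_MDM2_ARF 81
#define P_DN_WEE1 82
#define P_DN_ARF 83
#define P_RB_TOT 84
#define P_K_PHOS 85
#define P_KM_PHOS 86
#define P_K_DEPHOS 87
#define P_KI_RBP_P53 88
#define P_HI_RBP_P53 89
#define P_KF_RE 90
#define P_KD_RE 91
#define P_K_PHOS2 92
#define P_DN_E2F 93
#define P_DN_CDC 94
#define P_D_CDCI 95
#define P_KI_EBOX_MYC 96
#define P_HI_EBOX_MYC 97
#define P_VB_BMAL 98
#define P_V_BMAL 99
#define P_KA_BMAL_ROR 100
#define P_HA_BMAL_ROR 101
#define P_KI_BMAL_REV 102
#define P_HI_BMAL_REV 103
#define P_V_BMAL_E2F 104
#define P_KA_BMAL_E2F 105
#define P_HA_BMAL_E2F 106
#define P_KM_BMAL 107
#define P_DM_BMAL 108
#define P_VB_PER 109
#define P_V_PER 110
#define P_KA_PER_CB 111
#define P_HA_PER_CB 112
#define P_KI_PER_P53 113
#define P_HI_PER_P53 114
#define P_KM_PER 115
#define P_DM_PER 116
#define P_VB_CRY 117
#define P_V_CRY 118
#define P_KA_CRY_CB 119
#define P_HA_CRY_CB 120
#define P_KI_CRY_REV 121
#define P_HI_CRY_REV 122
#define P_KM_CRY 123
#define P_DM_CRY 124
#define P_VB_REV 125
#define P_V_REV 126
#define P_KA_REV_CB 127
#define P_HA_REV_CB 128
#define P_KM_REV 129
#define P_DM_REV 130
#define P_VB_ROR 131
#define P_V_ROR 132
#define P_KA_ROR_CB 133
#define P_HA_ROR_CB 134
#define P_KM_ROR 135
#define P_DM_ROR 136
#define P_KT_BMAL 137
#define P_KI_BMAL 138
#define P_DC_BMAL 139
#define P_KT_PER 140
#define P_KI_PER 141
#define P_DC_PER 142
#define P_KT_CRY 143
#define P_KI_CRY 144
#define P_DC_CRY 145
#define P_KT_REV 146
#define P_KI_REV 147
#define P_DC_REV 148
#define P_KT_ROR 149
#define P_KI_ROR 150
#define P_DC_ROR 151
#define P_DN_BMAL 152
#define P_K_CBFORM 153
#define P_DN_PER 154
#define P_DN_CRY 155
#define P_DN_REV 156
#define P_DN_ROR 157
#define P_KF_PC 158
#define P_KD_PC 159
#define P_KI_PC 160
#define P_DC_PERCRY 161
#define P_KF_PCN 162
#define P_KD_PCN 163
#define P_KE_PC 164
#define P_DN_PERCRY 165
#define P_KF_CBI 166
#define P_KD_CBI 167
#define P_D_CB 168
#define P_D_CBI 169
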
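outcome,group,mean,se,ci_lo,ci_hi
social_exclusion,unaffected,9.94,0.26,9.44,10.45
social_exclusion,internalising,12.16,1.38,9.45,14.87
social_exclusion,late_onset,12.43,0.41,11.63,13.23
social_exclusion,normative_maturing,12.45,0.88,10.72,14.18
social_exclusion,remitting,12.33,0.48,11.38,13.27
social_exclusion,remitting_ext,12.81,0.75,11.35,14.28
optimism,unaffected,12.96,0.28,12.41,13.51
optimism,internalising,11.91,1.24,9.48,14.34
optimism,late_onset,11.98,0.52,10.97,12.99
optimism,normative_maturing,11.70,0.79,10.16,13.24
optimism,remitting,12.15,0.59,11.00,13.30
optimism,remitting_ext,12.11,0.41,11.31,12.92
stress,unaffected,11.19,0.37,10.46,11.93
stress,internalising,11.95,0.53,10.90,12.99
stress,late_onset,11.64,0.91,9.85,13.42
stress,normative_maturing,12.16,0.86,10.47,13.84
stress,remitting,11.89,0.35,11.21,12.57
stress,remitting_ext,12.14,0.59,10.98,13.29
ipv_phys_perp,unaffected,6.99,0.30,6.40,7.58
ipv_phys_perp,internalising,7.90,0.54,6.85,8.96
ipv_phys_perp,late_onset,8.26,0.44,7.40,9.12
ipv_phys_perp,normative_maturing,7.93,0.47,7.00,8.85
ipv_phys_perp,remitting,8.00,0.19,7.63,8.38
ipv_phys_perp,remitting_ext,8.25,0.42,7.44,9.07
ipv_sex_perp,unaffected,4.20,0.29,3.63,4.76
ipv_sex_perp,internalising,4.43,0.10,4.23,4.62
ipv_sex_perp,late_onset,4.55,0.13,4.29,4.82
ipv_sex_perp,normative_maturing,4.44,0.16,4.13,4.75
ipv_sex_perp,remitting,4.51,0.15,4.21,4.80
ipv_sex_perp,remitting_ext,4.54,0.19,4.16,4.93
ipv_psych_perp,unaffected,3.82,0.23,3.36,4.28
ipv_psych_perp,internalising,4.48,0.37,3.77,5.20
ipv_psych_perp,late_onset,4.66,0.34,3.99,5.32
ipv_psych_perp,normative_maturing,4.49,0.47,3.57,5.41
ipv_psych_perp,remitting,4.57,0.33,3.93,5.21
ipv_psych_perp,remitting_ext,4.86,0.25,4.36,5.35
ipv_monit_perp,unaffected,6.54,0.28,5.99,7.09
ipv_monit_perp,internalising,7.59,0.69,6.23,8.94
ipv_monit_perp,late_onset,7.71,0.71,6.33,9.10
ipv_monit_perp,normative_maturing,7.45,0.64,6.20,8.70
ipv_monit_perp,remitting,7.58,0.70,6.21,8.94
ipv_monit_perp,remitting_ext,8.00,0.77,6.48,9.52
ipv_phys_vict,unaffected,7.44,0.51,6.45,8.43
ipv_phys_vict,internalising,8.75,1.03,6.74,10.77
ipv_phys_vict,late_onset,9.61,0.87,7.91,11.30
ipv_phys_vict,normative_maturing,8.95,0.95,7.09,10.80
ipv_phys_vict,remitting,9.44,0.53,8.40,10.47
ipv_phys_vict,remitting_ext,10.00,0.87,8.30,11.69
ipv_sex_vict,unaffected,4.71,0.38,3.97,5.44
ipv_sex_vict,internalising,5.30,0.79,3.76,6.84
ipv_sex_vict,late_onset,5.56,0.74,4.10,7.02
ipv_sex_vict,normative_maturing,5.41,0.49,4.44,6.38
ipv_sex_vict,remitting,5.48,0.49,4.53,6.44
ipv_sex_vict,remitting_ext,5.82,0.44,4.96,6.68
ipv_psych_vict,unaffected,4.26,0.23,3.81,4.72
ipv_psych_vict,internalising,5.05,0.44,4.19,5.92
ipv_psych_vict,late_onset,5.42,0.55,4.34,6.50
ipv_psych_vict,normative_maturing,5.14,0.47,4.22,6.06
ipv_psych_vict,remitting,5.49,0.44,4.63,6.35
ipv_psych_vict,remitting_ext,5.68,0.33,5.03,6.32
ipv_monit_vict,unaffected,6.87,0.24,6.39,7.34
ipv_monit_vict,internalising,8.59,0.66,7.30,9.87
ipv_monit_vict,late_onset,9.07,0.69,7.73,10.42
ipv_monit_vict,normative_maturing,8.54,0.66,7.24,9.84
ipv_monit_vict,remitting,8.86,0.61,7.66,10.06
ipv_monit_vict,remitting_ext,9.13,0.76,7.63,10.62
delinquency,unaffected,4.82,0.44,3.95,5.68
delinquency,internalising,7.31,0.89,5.56,9.06
delinquency,late_onset,8.97,0.91,7.18,10.75
delinquency,normative_maturing,7.33,0.49,6.38,8.28
delinquency,remitting,7.74,0.57,6.62,8.86
delinquency,remitting_ext,7.94,0.96,6.05,9.82
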
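"wavelength_nm","density"
770,0
772,0
774,0
776,0
778,0
780,1.73e-06
782,3.65e-06
784,7.55e-06
786,1.526e-05
788,3.019e-05
790,5.845e-05
792,0.00011073
794,0.0002053
796,0.00037246
798,0.00066126
800,0.00114883
802,0.00195312
804,0.00324937
806,0.00529006
808,0.00842782
810,0.01313901
812,0.02004484
814,0.0299251
816,0.04371811
818,0.0625
820,0.08743623
822,0.11970041
824,0.16035875
826,0.2102241
828,0.2696902
830,0.33856389
832,0.41591915
834,0.5
836,0.5881985
838,0.67712777
840,0.76279908
842,0.84089642
844,0.90712609
846,0.95760328
848,0.98922801
850,1
852,0.98922801
854,0.95760328
856,0.90712609
858,0.84089642
860,0.76279908
862,0.67712777
864,0.5881985
866,0.5
868,0.41591915
870,0.33856389
872,0.2696902
874,0.2102241
876,0.16035875
878,0.11970041
880,0.08743623
882,0.0625
884,0.04371811
886,0.0299251
888,0.02004484
890,0.01313901
892,0.00842782
894,0.00529006
896,0.00324937
898,0.00195312
900,0.00114883
902,0.00066126
904,0.00037246
906,0.0002053
908,0.00011073
910,5.845e-05
912,3.019e-05
914,1.526e-05
916,7.55e-06
918,3.65e-06
920,1.73e-06
922,0
924,0
926,0
928,0
930,0
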
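# synthetic RR interval series (seconds); two artifacts > 2 s
0.860
0.842
0.851
0.816
0.761
0.761
0.839
0.861
0.928
0.895
0.944
0.956
1.021
0.991
0.960
0.961
0.894
0.916
0.887
0.854
0.792
0.887
0.868
0.903
0.874
0.838
0.847
0.840
0.871
0.869
0.823
0.814
0.794
0.845
0.884
0.933
0.940
0.966
0.919
0.945
0.949
0.926
0.876
0.842
0.898
0.893
0.844
0.852
0.885
0.887
0.831
0.852
0.847
0.877
0.876
0.864
0.871
0.807
0.813
0.826
0.820
0.861
0.862
0.859
0.893
0.795
0.770
0.741
0.735
0.801
0.801
0.799
0.820
0.840
0.837
0.900
0.882
0.842
0.850
0.857
0.936
0.883
0.841
0.896
0.874
0.862
0.873
0.842
0.827
0.864
0.850
0.811
0.799
0.798
0.848
0.863
0.910
0.918
1.002
0.965
0.909
0.868
0.898
0.827
0.820
0.826
0.807
0.847
0.855
0.850
0.817
0.811
0.843
0.780
0.758
0.811
0.788
0.792
0.775
2.600
0.857
0.846
0.832
0.740
0.789
0.862
0.849
0.871
0.823
0.854
0.834
0.878
0.816
0.857
0.822
0.853
0.862
0.899
0.854
0.830
0.879
0.875
0.876
0.866
0.891
0.882
0.888
0.862
0.825
0.756
0.802
0.820
0.823
0.804
0.858
0.860
0.843
0.880
0.876
0.833
0.842
0.825
0.803
0.784
0.834
0.819
0.822
0.814
0.789
0.840
0.868
0.885
0.848
0.846
0.858
0.809
0.774
0.822
0.874
0.894
0.894
0.830
0.790
0.770
0.816
0.852
0.831
0.826
0.799
0.801
0.834
0.823
0.835
0.843
0.840
0.857
0.901
0.857
0.870
0.857
0.843
0.819
0.902
0.876
0.903
0.905
0.938
0.923
0.926
0.825
0.825
0.907
0.904
0.892
0.901
0.921
0.906
0.867
0.935
0.945
0.926
0.838
0.847
0.796
0.829
0.796
0.847
0.836
0.902
0.884
0.894
0.893
0.887
0.906
0.886
0.908
0.826
0.810
0.816
0.849
3.100
0.761
0.819
0.842
0.841
0.845
0.850
0.794
0.793
0.821
0.887
0.928
0.882
0.883
0.875
0.850
0.866
0.800
0.844
0.819
0.855
0.841
0.922
0.893
0.903
0.846
0.812
0.785
0.790
0.800
0.768
0.759
0.693
0.759
0.818
0.850
0.880
0.890
0.867
0.870
0.865
0.831
0.825
0.840
0.822
0.871
0.894
0.877
0.811
0.899
0.911
0.911
0.928
0.845
0.865
0.863
0.832
0.790
0.800
0.798
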